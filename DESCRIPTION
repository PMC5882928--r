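Package: mcstats
Title: Multidimensional Cluster Statistics for Labeled Point Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Permutation-based statistics for deciding whether labeled
    clusters of points in n-dimensional space are significantly disjoint.
    Implements a discrimination value built from mean intra- and
    inter-cluster Euclidean distances, label-permutation null
    distributions with exhaustive enumeration for small problems,
    preprocessing of multichannel electrophysiological recordings into
    windowed RMS state vectors, classical multidimensional scaling for
    trajectory and attractor-basin visualization, a discrimination-based
    rule for assigning new observations to clusters, and synthetic-data
    generators for labeled point clouds and multichannel recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
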