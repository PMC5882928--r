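#' Pairwise Euclidean distance matrix of a labeled point set
#'
#' Computes all pairwise Euclidean distances between the points. The
#' distance matrix — not the coordinates — is the sole input to every
#' downstream statistic, so the cluster test is invariant under rigid
#' motions of the data.
#'
#' @param points an [mcs_pointset()], or a bare numeric matrix.
#' @return a symmetric `M x M` numeric matrix with zero diagonal.
#' @examples
#' pairwise_distances(rbind(c(0, 0), c(3, 4)))
#' @export
pairwise_distances <- function(points) {
  coords <- if (inherits(points, "mcs_pointset")) points$coordinates
            else as.matrix(points)
  if (nrow(coords) < 2L) stop("at least 2 points are required")
  bad <- which(!apply(is.finite(coords), 1L, all))
  if (length(bad)) {
    stop("non-finite coordinate in row(s) ", paste(bad, collapse = ", "))
  }
  as.matrix(stats::dist(coords, method = "euclidean"))
}

#' Proximity matrix of mean intra- and inter-cluster distances
#'
#' Averages the pairwise Euclidean distances according to the points'
#' cluster labels. The main diagonal holds the mean intra-cluster
#' distances (self-pairs excluded: the mean for cluster A runs over the
#' `|A|(|A|-1)/2` unordered within-A pairs); each off-diagonal entry
#' `(A, B)` holds the mean over all `|A| * |B|` cross-cluster pairs. The
#' matrix is symmetric by construction.
#'
#' @param dist `M x M` distance matrix, e.g. from [pairwise_distances()].
#' @param labels length-`M` label vector.
#' @param label_order ordering of the distinct labels; defaults to order
#'   of first appearance.
#' @return an `L x L` numeric matrix with labels as dimnames, of class
#'   `mcs_proximity`.
#' @examples
#' ps <- mcs_pointset(rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2)),
#'                    c("A", "A", "B", "B"))
#' proximity_matrix(pairwise_distances(ps), ps$labels)
#' @export
proximity_matrix <- function(dist, labels, label_order = unique(labels)) {
  dist <- as.matrix(dist)
  labels <- as.character(labels)
  if (nrow(dist) != length(labels)) {
    stop("distance matrix has ", nrow(dist), " rows but ", length(labels),
         " labels were given")
  }
  label_order <- as.character(label_order)
  f <- factor(labels, levels = label_order)
  if (anyNA(f)) {
    stop("labels found that are absent from 'label_order': ",
         paste(unique(labels[is.na(f)]), collapse = ", "))
  }
  n <- as.integer(table(f))
  if (any(n < 2L)) {
    stop("degenerate cluster: label(s) ",
         paste(label_order[n < 2L], collapse = ", "),
         " have fewer than 2 points")
  }
  li <- as.integer(f)
  prox <- block_mean_distances(dist, li, length(label_order), n)
  dimnames(prox) <- list(label_order, label_order)
  class(prox) <- c("mcs_proximity", class(prox))
  prox
}

# L x L block means of a distance matrix given integer labels 1..L
# (diagonal: mean over unordered within pairs; off-diagonal: mean over
# all cross pairs). Shared by proximity_matrix() and the permutation
# engine.
block_mean_distances <- function(dist, li, L, n) {
  # block sums over ordered pairs: B[a, b] = sum_{i in a, j in b} d_ij
  B <- rowsum(t(rowsum(dist, li, reorder = TRUE)), li, reorder = TRUE)
  denom <- tcrossprod(n)          # n_a * n_b
  diag(denom) <- n * (n - 1L)     # ordered within pairs, diag zeros drop out
  B / denom
}

#' @export
print.mcs_proximity <- function(x, ...) {
  cat("Proximity matrix (diagonal: mean intra-cluster distances;",
      "off-diagonal: mean inter-cluster distances)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Discrimination value of two clusters
#'
#' The discrimination value of clusters A and B is
#' \deqn{\Delta(A,B) = d(A,A) + d(B,B) - 2\, d(A,B)}
#' where `d(A,A)` and `d(B,B)` are the mean intra-cluster distances and
#' `d(A,B)` the mean inter-cluster distance. The inter-cluster term is
#' weighted by 2 to balance the one inter-cluster block against the two
#' intra-cluster blocks. Geometrically, drawing each cluster as a disk of
#' diameter equal to its mean intra-cluster distance centered at distance
#' `d(A,B)` from the other: the disks are disjoint when `Delta < 0` and
#' overlap when `Delta > 0`. The more negative `Delta`, the denser and/or
#' better separated the clusters.
#'
#' @param prox proximity matrix from [proximity_matrix()].
#' @param a,b two distinct labels present in the proximity matrix.
#' @return scalar discrimination value; symmetric in `(a, b)`.
#' @examples
#' ps <- mcs_pointset(rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2)),
#'                    c("A", "A", "B", "B"))
#' prox <- proximity_matrix(pairwise_distances(ps), ps$labels)
#' discrimination_value(prox, "A", "B")  # negative: disjoint
#' @export
discrimination_value <- function(prox, a, b) {
  a <- as.character(a); b <- as.character(b)
  if (identical(a, b)) stop("'a' and 'b' must be two distinct labels")
  labs <- rownames(prox)
  if (!all(c(a, b) %in% labs)) {
    stop("label(s) not in proximity matrix: ",
         paste(setdiff(c(a, b), labs), collapse = ", "))
  }
  unname(prox[a, a] + prox[b, b] - 2 * prox[a, b])
}

#' Global discrimination value over all clusters
#'
#' Aggregates the pairwise discrimination values into a single number
#' quantifying how well all `L` clusters separate jointly:
#' \deqn{\Delta_{global} = \sum_{a < b} \Delta(a, b)}
#' the sum over all unordered label pairs. For `L = 2` this reduces
#' exactly to [discrimination_value()]. The sum keeps the per-pair
#' factor-2 balance between intra- and inter-cluster terms.
#'
#' @param prox proximity matrix from [proximity_matrix()].
#' @return scalar global discrimination value.
#' @export
global_discrimination <- function(prox) {
  L <- nrow(prox)
  if (L < 2L) stop("at least 2 labels are required")
  delta_global_from_blocks(unclass(prox))
}

# sum over unordered pairs of d(a,a) + d(b,b) - 2 d(a,b), given the
# L x L matrix of block mean distances
delta_global_from_blocks <- function(P) {
  L <- nrow(P)
  (L - 1) * sum(diag(P)) - 2 * sum(P[upper.tri(P)])
}
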