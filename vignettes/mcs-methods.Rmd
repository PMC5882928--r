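---
title: "Multidimensional cluster statistics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional cluster statistics: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcstats)
```

## The question the statistic answers

Given `M` points in `n`-dimensional space, each labeled with one of `L`
known experimental conditions, are the condition-wise clusters
significantly *disjoint*? The motivating application is neural state-space
analysis: each point is a spatial activity pattern (for instance the
per-channel RMS amplitude of a multichannel cortical recording inside one
time window), and the question is whether sustained stimulus conditions
occupy distinguishable regions of state space. The method is, however,
agnostic to where the feature vectors come from.

This is not clustering: the labels are known, and the statistic evaluates
their geometric separation. It is closest in spirit to distance-based
multivariate tests such as PERMANOVA, but uses a different statistic with
a direct geometric reading.

## The discrimination value

All computation starts from the matrix of pairwise Euclidean distances.
Averaging those distances by label pair gives the *proximity matrix*: the
diagonal entry for cluster A is the mean over the `|A|(|A|-1)/2` distinct
within-A pairs (self-distances are not pairs of points and are excluded —
including the diagonal zeros would understate every cluster's spread);
the off-diagonal entry for (A, B) is the mean over all `|A||B|` cross
pairs.

The **discrimination value** of two clusters is

$$\Delta(A,B) = d(A,A) + d(B,B) - 2\,d(A,B),$$

with `d(·,·)` the proximity entries. The factor 2 balances the single
inter-cluster term against the two intra-cluster terms. Drawing each
cluster as a disk of diameter equal to its mean intra-cluster distance,
centered `d(A,B)` apart, gives the geometric reading: the disks are
disjoint exactly when $\Delta < 0$ and overlap when $\Delta > 0$; more
negative means denser and/or further apart.

For `L > 2` clusters the package uses a **global discrimination value**:
the sum of $\Delta(a,b)$ over all unordered label pairs. This reduces
exactly to the two-cluster definition at `L = 2` and preserves the
per-pair factor-2 balance. Other aggregates (e.g. the mean, or a
worst-pair maximum) are defensible; the sum was chosen because it keeps
the statistic extensive in the number of separating pairs and is isolated
behind `global_discrimination()` so it can be swapped without touching
the permutation machinery. Block means are unweighted by cluster size:
the factor 2 already compensates for pair-count imbalance at the block
level, and plain block means make $\Delta$ independent of relative
cluster sizes.

Because $\Delta$ depends on the data only through pairwise distances, it
is invariant under translation, rotation and reflection, and scales
linearly when all coordinates are scaled — both properties are enforced
by tests.

## The permutation test

Under the null hypothesis that labels are exchangeable, the observed
$\Delta_0$ is compared with the distribution of $\Delta$ under random
relabelings of the points with all class sizes preserved. Small
(negative) $\Delta_0$ relative to that null indicates disjoint clusters.

* **Number of permutations.** The default is $N = 10^4$. With `M` points
  and `L` labels there are up to $L^M$ configurations, so exhaustive
  sampling is usually impossible; however, when the number of *distinct*
  count-preserving labelings is at most `N` (small samples), the package
  enumerates them all and the p-value is exact. Permutations are
  otherwise sampled with replacement from the space of count-preserving
  shuffles.
* **p-value estimator.** The literal definition
  $p = \Pr(X < \Delta_0)$ — the empirical probability of finding a
  better labeling by chance — can return exactly 0, which is not a valid
  permutation p-value. The default is therefore the add-one estimator
  $(1 + \#\{\Delta_i \le \Delta_0\})/(N+1)$, bounded below by
  $1/(N+1)$; the strict mode remains available as
  `comparison_mode = "paper_literal_strict"` for replication.
* **Tie tolerance.** Relabelings equivalent to the original by symmetry
  (for instance swapping the two labels wholesale) reproduce $\Delta_0$
  only up to floating-point round-off; comparisons therefore treat
  values within a relative $10^{-8}$ of $\Delta_0$ as ties. Real data
  produce no other values that close.
* **Reproducibility.** Each test invocation seeds its own generator from
  the configuration and restores the global RNG state, so a fixed seed
  gives bit-identical results. `pairwise_pvalue_matrix()` derives one
  seed per label pair from the configured seed, making each entry
  independent of evaluation order. The pairwise matrix reports raw
  mutual p-values by default; Holm–Bonferroni adjustment is available
  but off by default.

### Exchangeability, autocorrelation and the block shuffle

The test assumes the labels are exchangeable under the null. State
vectors produced by *overlapping* sliding windows (the default 20 s
window advanced in 5 s steps shares 75 % of its samples with its
neighbour) are strongly autocorrelated, and full-shuffle permutation is
then anticonservative: on synthetic recordings with no condition
information at all, it rejects far above the nominal level. Users should
treat p-values from overlapping-window pipelines as optimistic and have
two remedies, both provided:

* non-overlapping windows (`step >= window`), which restore
  exchangeability at the cost of fewer state vectors — the package's
  null-calibration tests use this design;
* `scheme = "block_shuffle"`, which permutes contiguous blocks of
  observations as units and respects serial dependence (choose
  `block_length` on the order of the windows per condition segment).

The default remains the full shuffle, which replicates the published
procedure; the choice is a documented trade-off, not an endorsement of
the exchangeability assumption for overlapping windows.

## Preprocessing multichannel recordings

The chain `exclude_onset() |> sliding_rms() |> zscore_states() |>
build_pointset()` turns condition-labeled multichannel segments into a
labeled point set:

* **Onset exclusion** (default 0.2 s) removes the evoked transient after
  each stimulus change, once per condition segment; the analysis targets
  sustained activity. Note that a 180 s block then yields 32 full
  20 s/5 s windows; without onset exclusion the closed form
  `floor((180 - 20)/5) + 1 = 33` applies, and eight three-minute blocks
  give `M = 264` points.
* **Sliding RMS** (defaults: 20 s windows, 5 s steps) computes one RMS
  amplitude per channel per window over half-open sample intervals
  `[t, t + w)`; only full windows are emitted, so estimates are equally
  precise everywhere and windows never span condition boundaries.
* **Z-scoring** standardizes each state vector *across its channels*
  (mean 0, SD 1 per window). This orientation — rather than per channel
  over time — is what removes activity common to all channels, so that
  only the spatial pattern of activation distinguishes conditions and a
  global amplitude change cannot masquerade as a pattern difference. The
  per-channel-over-time alternative is available via
  `orientation = "time"` for comparison. A window with zero
  across-channel variance has no pattern and is reported as an error
  naming the window.

## Visualization

Classical (Torgerson) metric MDS — double centering of squared distances
followed by eigendecomposition — projects points or cluster centroids to
the plane for display. It is deterministic (no random initialization,
unlike SMACOF-style stress majorization) and exact for configurations of
rank ≤ 2; for genuinely high-dimensional data some distortion is
inevitable, so the residual distortion is reported as a stress value
rather than silently ignored. Negative eigenvalues are truncated to
zero. Reflection indeterminacy is removed by a fixed convention (axes in
decreasing-eigenvalue order; each axis signed so its largest-magnitude
coordinate is positive), making figures and coordinates reproducible.

The "attractor basin" view draws each cluster as a disk at its
MDS-embedded centroid (from the proximity off-diagonals) with diameter
equal to its mean intra-cluster distance. Visualization never feeds back
into inference: the statistics are computed from the full-dimensional
distances, and the pipeline produces bit-identical test results with
plotting on or off (asserted by tests).

## Assigning new points

A new point `x` is tentatively appended to each cluster in turn; each
assignment's global discrimination value is computed, and `x` goes to
the cluster whose assignment minimizes it. The tentative point
participates in that cluster's intra-cluster distances and in all of its
inter-cluster distances. The implementation updates the reference block
sums incrementally (cost `O(M)` per candidate label after a one-off
`O(M^2)` precomputation) and matches a full recomputation to numerical
round-off. Ties — possible only for exactly symmetric configurations —
are broken by canonical label order with a warning. On balanced
spherical clusters this rule behaves like nearest-centroid
classification at large separation, which the tests use as a sanity
link; it is not a calibrated classifier and reports a margin, not a
probability.

## Synthetic data

The generators exist so that every statistical property of the method is
testable without any recording on disk.

* `make_gaussian_clusters()` places `k` centroids on a regular simplex —
  so "separation" is a single knob, the common distance between all
  centroid pairs in units of the within-cluster σ — and draws spherical
  (or full-covariance) Gaussian points. Separation 0 gives exchangeable
  null data for calibration.
* `make_attractor_trajectory()` is a discrete mean-reverting
  (Ornstein–Uhlenbeck-type) process pulled toward the active condition's
  centroid, switching conditions on a dwell schedule: with zero noise the
  distance to the target decays geometrically by `1 - relaxation_rate`
  per step, and repeated conditions revisit their basin.
* `make_recording()` builds condition blocks as common mode +
  rank-one spatial pattern × band-limited noise carrier + white sensor
  noise, at a default 100 Hz sampling rate and 180 s blocks (the state
  vectors are 20-s RMS amplitudes, for which this rate fully resolves
  the carrier's amplitude dynamics). A noise carrier rather than a pure
  tone makes the windowed RMS a stationary amplitude estimate that
  cannot phase-lock to the window grid. Default spatial patterns are
  unit-norm raised-cosine bumps on disjoint channel groups (tonotopy
  like): disjoint supports are orthogonal *and* differ in per-channel
  magnitude, which is what an RMS pipeline can see — sign-flip
  orthogonal patterns would be invisible to it. With
  `power_matched = TRUE` (default) spatially white compensation noise is
  added to lower-power conditions so the expected per-channel mean
  square is equal across conditions: overall amplitude then carries no
  condition information and only the spatial pattern separates the
  conditions, which is precisely the regime the statistic exists for.

What the generators deliberately do not emulate: 1/f spectra, volume
conduction, non-stationarity within a block, artifacts. Passing tests on
this synthetic family shows the statistic behaves as designed under its
own assumptions; it does not certify calibration on real recordings,
where serial dependence (above) is the dominant caveat.

## Problem sizes used in the checks

The package's own acceptance checks run at the scale the method is meant
for: two 16-dimensional clusters of 100 points each (type-I calibration
over 1,000 replicates at `N = 999`; detection at separation 5σ with
`N = 10^4`), 20 small instances (`M ≤ 10`) comparing Monte-Carlo against
exhaustive p-values, and 100 end-to-end replicates of two-condition,
16-channel, four-block power-matched recordings. These sizes were chosen
to keep Monte-Carlo error well below the decision thresholds they feed.

## Known limitations

* Exchangeability is the load-bearing assumption; overlapping-window
  pipelines violate it (see above).
* The global statistic sums pairwise discrimination values, so one
  widely separated pair can mask one overlapping pair; use
  `pairwise_pvalue_matrix()` alongside the global test.
* $\Delta$ has no scale-free calibration — only its sign and its rank
  within the permutation null are interpretable.
* Classical MDS figures understate distances for high-rank data; check
  the reported stress before reading geometry off a plot.
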