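# Vertices of a regular (k-1)-simplex embedded in `dim` dimensions with
# edge length `edge`, centered at the origin.
simplex_centroids <- function(k, dim, edge) {
  if (k == 1L) return(matrix(0, 1L, dim))
  if (dim < k - 1L) {
    stop("dimension ", dim, " too small for a regular simplex of ", k,
         " vertices (need at least ", k - 1L, ")")
  }
  V <- diag(k)
  V <- sweep(V, 2L, colMeans(V))          # center: rank k-1
  sv <- svd(V, nu = 0L, nv = k - 1L)
  X <- V %*% sv$v                         # k x (k-1), edge sqrt(2)
  X <- X * edge / sqrt(2)
  cbind(X, matrix(0, k, dim - (k - 1L)))
}

#' Generate labeled Gaussian clusters
#'
#' Draws `points_per_cluster` observations around each of `n_clusters`
#' centroids placed at the vertices of a regular simplex, so that every
#' pair of centroids is separated by `separation * sigma`. Points are
#' i.i.d. Gaussian with standard deviation `sigma` per coordinate
#' (spherical) or with the supplied covariance matrix. With
#' `separation = 0` all clusters share one distribution, giving
#' exchangeable null data for calibration checks.
#'
#' @param n_clusters number of clusters `k` (labels `A`, `B`, ...).
#' @param points_per_cluster observations per cluster (at least 2).
#' @param dimension dimensionality `n` (at least `k - 1` for the simplex
#'   layout).
#' @param separation centroid separation in units of the within-cluster
#'   standard deviation.
#' @param sigma within-cluster standard deviation (default 1).
#' @param covariance optional full covariance matrix (overrides `sigma`
#'   for the point noise; `separation` stays in units of `sigma`).
#' @param seed optional RNG seed (restored on exit).
#' @return an [mcs_pointset()] with `k * points_per_cluster` rows.
#' @examples
#' ps <- make_gaussian_clusters(2, 10, dimension = 4, separation = 5,
#'                              seed = 1)
#' @export
make_gaussian_clusters <- function(n_clusters = 2L, points_per_cluster = 100L,
                                   dimension = 16L, separation = 5,
                                   sigma = 1, covariance = NULL,
                                   seed = NULL) {
  stopifnot(n_clusters >= 1L, points_per_cluster >= 2L, separation >= 0,
            sigma > 0)
  centroids <- simplex_centroids(n_clusters, dimension, separation * sigma)
  labs <- make.unique(rep(LETTERS, length.out = n_clusters), sep = "")
  with_config_seed(seed, {
    blocks <- lapply(seq_len(n_clusters), function(k) {
      Z <- matrix(stats::rnorm(points_per_cluster * dimension),
                  points_per_cluster, dimension)
      noise <- if (is.null(covariance)) sigma * Z else Z %*% chol(covariance)
      sweep(noise, 2L, centroids[k, ], "+")
    })
    mcs_pointset(do.call(rbind, blocks),
                 rep(labs, each = points_per_cluster),
                 label_order = labs)
  })
}

#' Generate a noisy attractor-hopping trajectory
#'
#' Simulates a discrete mean-reverting (Ornstein-Uhlenbeck-type) process
#' in state space: at every step the state moves a fraction
#' `relaxation_rate` of the way toward the centroid of the currently
#' active condition and receives isotropic Gaussian noise. The active
#' condition switches after `dwell_steps` steps according to `schedule`.
#' This emulates trajectories that converge to, and persist within,
#' condition-specific regions of state space, and that return to the same
#' region when a condition is repeated.
#'
#' @inheritParams make_gaussian_clusters
#' @param dwell_steps steps spent in each scheduled condition block.
#' @param relaxation_rate pull strength per step, in `(0, 1]`. With zero
#'   noise the distance to the centroid decays geometrically by the
#'   factor `1 - relaxation_rate` per step.
#' @param noise_sd step noise standard deviation per coordinate.
#' @param schedule vector of condition indices (1-based) giving the block
#'   order; default visits each condition twice.
#' @param x0 starting state (default: origin).
#' @return a list with `positions` (steps x dimension), `labels` (active
#'   condition per step), `centroids`, `schedule`.
#' @export
make_attractor_trajectory <- function(n_clusters = 3L, dimension = 16L,
                                      separation = 5, sigma = 1,
                                      dwell_steps = 50L,
                                      relaxation_rate = 0.2,
                                      noise_sd = 0.1,
                                      schedule = NULL, x0 = NULL,
                                      seed = NULL) {
  stopifnot(relaxation_rate > 0, relaxation_rate <= 1, dwell_steps >= 1L,
            noise_sd >= 0)
  centroids <- simplex_centroids(n_clusters, dimension, separation * sigma)
  labs <- make.unique(rep(LETTERS, length.out = n_clusters), sep = "")
  if (is.null(schedule)) schedule <- rep(seq_len(n_clusters), times = 2L)
  active <- rep(schedule, each = dwell_steps)
  steps <- length(active)
  if (is.null(x0)) x0 <- numeric(dimension)
  with_config_seed(seed, {
    pos <- matrix(0, steps, dimension)
    x <- as.numeric(x0)
    for (t in seq_len(steps)) {
      target <- centroids[active[t], ]
      x <- x + relaxation_rate * (target - x) +
        noise_sd * stats::rnorm(dimension)
      pos[t, ] <- x
    }
    list(positions = pos, labels = labs[active], centroids = centroids,
         schedule = labs[schedule])
  })
}

#' Unit-norm spatial activation patterns on disjoint channel groups
#'
#' Builds one raised-cosine activation bump per condition, each occupying
#' its own contiguous group of channels (mimicking, e.g., tonotopically
#' separated activation sites). The patterns are mutually orthogonal and
#' share the same magnitude profile, so per-channel RMS amplitudes can
#' distinguish the conditions while the total power cannot.
#'
#' @param channels number of recording channels.
#' @param k number of patterns (must satisfy `k <= channels`).
#' @return a `k x channels` matrix with unit-norm rows.
#' @export
condition_patterns <- function(channels, k) {
  stopifnot(k >= 1L, k <= channels)
  width <- channels %/% k
  P <- matrix(0, k, channels)
  for (i in seq_len(k)) {
    idx <- ((i - 1L) * width + 1L):(i * width)
    bump <- sin(pi * seq_along(idx) / (length(idx) + 1))
    P[i, idx] <- bump / sqrt(sum(bump^2))
  }
  P
}

# band-limited unit-RMS noise: white noise smoothed with a moving
# average of `smooth_s` seconds
bandlimited_noise <- function(n, rate, smooth_s = 0.05) {
  k <- max(1L, round(smooth_s * rate))
  x <- stats::rnorm(n + k - 1L)
  x <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 1L))[k:(n + k - 1L)]
  x / sqrt(mean(x^2))
}

#' Generate a multichannel recording with condition-specific patterns
#'
#' Simulates condition blocks of a multichannel recording. Each block's
#' channel signals are the sum of a common-mode component (identical in
#' every channel), a condition-specific rank-one component — a unit-norm
#' spatial pattern times a band-limited noise carrier scaled by
#' `modulation_depth` — and white sensor noise. A band-limited noise
#' carrier (rather than a pure tone) makes the windowed RMS a stable
#' amplitude estimate that cannot lock to carrier phase.
#'
#' With `power_matched = TRUE` (default), spatially white compensation
#' noise is added to lower-power conditions so the expected per-channel
#' mean square is equal across conditions: the overall amplitude then
#' carries no condition information and only the spatial pattern of
#' activation distinguishes the conditions — the regime the cluster
#' statistics are designed for.
#'
#' @param channels number of channels (default 16).
#' @param sampling_rate Hz (default 100; the analysis operates on 20-s
#'   RMS amplitudes, for which this fully resolves the carrier dynamics).
#' @param block_duration_s duration of each condition block in seconds
#'   (default 180, i.e. three-minute blocks).
#' @param conditions condition labels (default `c("A", "B")`).
#' @param patterns matrix of unit-norm spatial patterns, one row per
#'   condition (default [condition_patterns()]).
#' @param modulation_depth pattern amplitude, recycled over conditions
#'   (default 1; use 0 for a condition with no spatial information, e.g.
#'   silence).
#' @param common_mode_amplitude amplitude of the shared component
#'   (default 1).
#' @param noise_sd white sensor-noise standard deviation (default 0.5).
#' @param schedule vector of condition labels giving the block order
#'   (default: all conditions, repeated twice).
#' @param power_matched equalize expected total power across conditions
#'   (default `TRUE`).
#' @param seed optional RNG seed (restored on exit).
#' @return a list with `segments` (list of [recording_segment()]s in
#'   schedule order) and `schedule` (data frame `label,start_s,end_s`,
#'   half-open intervals).
#' @export
make_recording <- function(channels = 16L, sampling_rate = 100,
                           block_duration_s = 180,
                           conditions = c("A", "B"),
                           patterns = NULL, modulation_depth = 1,
                           common_mode_amplitude = 1, noise_sd = 0.5,
                           schedule = NULL, power_matched = TRUE,
                           seed = NULL) {
  stopifnot(block_duration_s > 0, channels >= 2L)
  k <- length(conditions)
  if (is.null(patterns)) patterns <- condition_patterns(channels, k)
  patterns <- as.matrix(patterns)
  if (nrow(patterns) != k || ncol(patterns) != channels) {
    stop("'patterns' must be a ", k, " x ", channels, " matrix")
  }
  nrm <- sqrt(rowSums(patterns^2))
  if (any(abs(nrm[nrm > 0] - 1) > 1e-8)) {
    stop("spatial patterns must have unit norm")
  }
  depth <- rep_len(modulation_depth, k)
  names(depth) <- conditions
  if (is.null(schedule)) schedule <- rep(conditions, times = 2L)
  if (!all(schedule %in% conditions)) {
    stop("schedule contains unknown condition labels")
  }
  # expected per-channel mean square: cm^2 + depth^2/C + noise^2 (+ comp)
  comp_var <- stats::setNames(numeric(k), conditions)
  if (power_matched) {
    comp_var[] <- (max(depth^2) - depth^2) / channels
  }
  TT <- round(block_duration_s * sampling_rate)
  with_config_seed(seed, {
    segments <- vector("list", length(schedule))
    t0 <- 0
    for (b in seq_along(schedule)) {
      lab <- schedule[b]
      ci <- match(lab, conditions)
      cm <- common_mode_amplitude * bandlimited_noise(TT, sampling_rate)
      carrier <- depth[ci] * bandlimited_noise(TT, sampling_rate)
      X <- matrix(cm, channels, TT, byrow = TRUE) +
        outer(patterns[ci, ], carrier) +
        matrix(stats::rnorm(channels * TT, sd = noise_sd), channels, TT)
      if (comp_var[ci] > 0) {
        X <- X + matrix(stats::rnorm(channels * TT,
                                     sd = sqrt(comp_var[ci])),
                        channels, TT)
      }
      segments[[b]] <- recording_segment(X, sampling_rate, lab,
                                         start_time = t0)
      t0 <- t0 + TT / sampling_rate
    }
    starts <- vapply(segments, `[[`, numeric(1), "start_time")
    list(segments = segments,
         schedule = data.frame(label = schedule, start_s = starts,
                               end_s = starts + TT / sampling_rate))
  })
}
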