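#' Construct a recording segment
#'
#' One condition block of a multichannel recording: a channels-by-time
#' sample matrix with its sampling rate, condition label and start time
#' within the full recording.
#'
#' @param samples numeric matrix, channels (rows) by time samples
#'   (columns), amplitude in recording units.
#' @param sampling_rate sampling rate in Hz.
#' @param condition condition label of the block.
#' @param start_time start of the block in seconds relative to the
#'   recording origin.
#' @return an object of class `mcs_segment`.
#' @export
recording_segment <- function(samples, sampling_rate, condition,
                              start_time = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!all(is.finite(samples))) stop("non-finite sample values in segment")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("'sampling_rate' must be positive")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         condition = as.character(condition), start_time = start_time),
    class = "mcs_segment")
}

#' @export
print.mcs_segment <- function(x, ...) {
  cat("Recording segment '", x$condition, "': ", nrow(x$samples),
      " channels x ", ncol(x$samples), " samples (",
      format(ncol(x$samples) / x$sampling_rate), " s at ",
      x$sampling_rate, " Hz, t0 = ", format(x$start_time), " s)\n",
      sep = "")
  invisible(x)
}

segment_duration <- function(segment) {
  ncol(segment$samples) / segment$sampling_rate
}

#' Exclude the stimulus-onset transient from a segment
#'
#' Evoked onset responses in the first fraction of a second after a
#' stimulus change are transients unrelated to the sustained activity
#' under study; they are removed once per condition segment before
#' windowing. The default removes the first 200 ms.
#'
#' @param segment an [recording_segment()].
#' @param exclusion seconds to drop from the start of the segment
#'   (default 0.2).
#' @return the shortened segment; its `start_time` is shifted by
#'   `exclusion` so window times stay aligned to the recording origin.
#' @export
exclude_onset <- function(segment, exclusion = 0.2) {
  stopifnot(inherits(segment, "mcs_segment"))
  if (exclusion < 0) stop("'exclusion' must be non-negative")
  if (exclusion == 0) return(segment)
  if (exclusion >= segment_duration(segment)) {
    stop("onset exclusion (", exclusion, " s) leaves an empty segment (",
         "duration ", format(segment_duration(segment)), " s)")
  }
  nskip <- round(exclusion * segment$sampling_rate)
  recording_segment(
    segment$samples[, -seq_len(nskip), drop = FALSE],
    segment$sampling_rate, segment$condition,
    start_time = segment$start_time + nskip / segment$sampling_rate)
}

#' Sliding-window RMS state vectors of a segment
#'
#' Moves a window of `window_length` seconds through the segment in steps
#' of `step` seconds and computes, per channel, the root-mean-square
#' amplitude of the samples inside each window. Each window yields one
#' state vector whose dimension equals the channel count. Only windows
#' lying entirely inside the segment are emitted, so windows never span
#' condition boundaries; with `T` samples, window length `w` and step
#' `s` (in samples) the number of windows is `floor((T - w)/s) + 1`.
#' Windows are half-open sample intervals `[t, t + w)`.
#'
#' @param segment an [recording_segment()].
#' @param window_length window width in seconds (default 20).
#' @param step window shift in seconds (default 5).
#' @return an object of class `mcs_states`: a list with `vectors` (one
#'   row per window, one column per channel), `window_centers` (seconds),
#'   `condition`, `window_length`, `step`, and `zscored`. A segment
#'   shorter than one window yields a zero-row series with a warning.
#' @export
sliding_rms <- function(segment, window_length = 20, step = 5) {
  stopifnot(inherits(segment, "mcs_segment"))
  if (step <= 0) stop("'step' must be positive")
  rate <- segment$sampling_rate
  wlen <- round(window_length * rate)
  slen <- round(step * rate)
  if (wlen < 1L || slen < 1L) {
    stop("window and step must span at least one sample")
  }
  TT <- ncol(segment$samples)
  if (wlen > TT) {
    warning("segment shorter than one window (", format(TT / rate),
            " s < ", window_length, " s): empty state-vector series")
    W <- 0L
    starts <- integer(0)
  } else {
    W <- (TT - wlen) %/% slen + 1L
    starts <- (seq_len(W) - 1L) * slen        # 0-based sample offsets
  }
  C <- nrow(segment$samples)
  vectors <- matrix(0, nrow = W, ncol = C)
  if (W > 0L) {
    for (c in seq_len(C)) {
      cs <- c(0, cumsum(segment$samples[c, ]^2))
      vectors[, c] <- sqrt((cs[starts + wlen + 1L] - cs[starts + 1L]) / wlen)
    }
  }
  colnames(vectors) <- rownames(segment$samples)
  structure(
    list(vectors = vectors,
         window_centers = segment$start_time + (starts + wlen / 2) / rate,
         condition = segment$condition,
         window_length = window_length, step = step, zscored = FALSE),
    class = "mcs_states")
}

#' @export
print.mcs_states <- function(x, ...) {
  cat("State-vector series '", x$condition, "': ", nrow(x$vectors),
      " windows x ", ncol(x$vectors), " channels (",
      x$window_length, " s windows, ", x$step, " s steps",
      if (x$zscored) ", z-scored", ")\n", sep = "")
  invisible(x)
}

#' Z-score state vectors
#'
#' Standardizes each state vector across its channels: per window, the
#' mean over channels is subtracted and the result divided by the
#' standard deviation over channels. This removes activity common to all
#' channels (global amplitude fluctuations), leaving only the spatial
#' pattern of activation. The alternative orientation
#' (`orientation = "time"`: each channel standardized over the windows of
#' the series) is provided for comparison but does not remove
#' common-mode activity.
#'
#' @param series an `mcs_states` object from [sliding_rms()].
#' @param orientation `"channels"` (default, across channels within each
#'   window) or `"time"` (per channel over the series' windows).
#' @return the series with standardized `vectors`.
#' @export
zscore_states <- function(series, orientation = c("channels", "time")) {
  stopifnot(inherits(series, "mcs_states"))
  orientation <- match.arg(orientation)
  V <- series$vectors
  if (ncol(V) < 2L) stop("at least 2 channels are required for z-scoring")
  if (orientation == "channels") {
    mu <- rowMeans(V)
    sdv <- apply(V, 1L, stats::sd)
    degenerate <- which(sdv == 0)
    if (length(degenerate)) {
      stop("zero across-channel variance in window(s) ",
           paste(degenerate, collapse = ", "))
    }
    series$vectors <- (V - mu) / sdv
  } else {
    mu <- colMeans(V)
    sdv <- apply(V, 2L, stats::sd)
    degenerate <- which(sdv == 0)
    if (length(degenerate)) {
      stop("zero temporal variance in channel(s) ",
           paste(degenerate, collapse = ", "))
    }
    series$vectors <- sweep(sweep(V, 2L, mu), 2L, sdv, "/")
  }
  series$zscored <- TRUE
  series
}

#' Concatenate state-vector series into a labeled point set
#'
#' Stacks the series' state vectors in time order, labeling each window
#' with its series' condition, and records the segment of origin of every
#' point. The result is the input of the cluster statistics and of the
#' trajectory visualization.
#'
#' @param series_list a list of `mcs_states` objects sharing the same
#'   channel count.
#' @return an [mcs_pointset()] with `M = ` total window count.
#' @export
build_pointset <- function(series_list) {
  if (inherits(series_list, "mcs_states")) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, logical(1), "mcs_states")))
  C <- vapply(series_list, function(s) ncol(s$vectors), integer(1))
  if (length(unique(C)) != 1L) {
    stop("channel-count mismatch across series: ",
         paste(unique(C), collapse = ", "))
  }
  conds <- vapply(series_list, `[[`, character(1), "condition")
  W <- vapply(series_list, function(s) nrow(s$vectors), integer(1))
  per_cond <- tapply(W, conds, sum)
  if (any(per_cond < 2L)) {
    stop("condition(s) ", paste(names(per_cond)[per_cond < 2L],
                                collapse = ", "),
         " contribute fewer than 2 windows")
  }
  coords <- do.call(rbind, lapply(series_list, `[[`, "vectors"))
  labels <- rep(conds, W)
  origin <- rep(seq_along(series_list), W)
  centers <- unlist(lapply(series_list, `[[`, "window_centers"),
                    use.names = FALSE)
  mcs_pointset(coords, labels, label_order = unique(conds),
               origin = origin, window_centers = centers)
}
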