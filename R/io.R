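# sniff comma vs tab from the header line
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a labeled point set from delimited text
#'
#' The file dialect is a header row, `n` numeric coordinate columns named
#' `d1..dn`, and a final column named `label`; rows are observations in
#' time order. Comma and tab delimiters are auto-detected.
#'
#' @param path path to the file.
#' @return an [mcs_pointset()].
#' @export
read_pointset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_sep(path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed point-set file '", path, "': ",
                             conditionMessage(e)))
  if (!"label" %in% names(df)) {
    stop("point-set file '", path, "' has no 'label' column")
  }
  coord_cols <- setdiff(names(df), "label")
  if (!length(coord_cols)) stop("no coordinate columns in '", path, "'")
  coords <- suppressWarnings(
    vapply(df[coord_cols], as.numeric, numeric(nrow(df))))
  coords <- matrix(coords, nrow = nrow(df),
                   dimnames = list(NULL, coord_cols))
  bad <- which(!apply(is.finite(coords), 1L, all))
  if (length(bad)) {
    stop("non-numeric or non-finite coordinate in '", path, "', line(s) ",
         paste(bad + 1L, collapse = ", "), " (counting the header)")
  }
  mcs_pointset(coords, as.character(df$label))
}

#' Write a labeled point set to delimited text
#'
#' @param points an [mcs_pointset()].
#' @param path output path; `.tsv` extension selects tab delimiting,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_pointset <- function(points, path) {
  stopifnot(inherits(points, "mcs_pointset"))
  coords <- points$coordinates
  # %.17g keeps the full double precision so read -> write round-trips
  fmt <- matrix(sprintf("%.17g", coords), nrow = nrow(coords),
                dimnames = list(NULL, paste0("d", seq_len(ncol(coords)))))
  df <- data.frame(fmt, label = points$labels, check.names = FALSE,
                   stringsAsFactors = FALSE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a square labeled matrix (distance or proximity) as delimited text
#'
#' @param m matrix with label dimnames (e.g. from [proximity_matrix()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(m, path) {
  utils::write.table(data.frame(label = rownames(m), unclass(m),
                                check.names = FALSE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multichannel recording and its condition schedule
#'
#' The recording file is delimited text with one row per time sample and
#' one column per channel; the schedule sidecar has columns
#' `label,start_s,end_s` with half-open `[start, end)` intervals in
#' seconds. Intervals must not overlap and must lie within the recording.
#'
#' @param path recording file.
#' @param rate sampling rate in Hz.
#' @param schedule_path schedule sidecar file.
#' @return a list of [recording_segment()]s in schedule order.
#' @export
read_recording <- function(path, rate, schedule_path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(schedule_path)) {
    stop("schedule file not found: ", schedule_path)
  }
  sep <- sniff_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep)
  X <- t(as.matrix(raw))                     # channels x time
  sched <- utils::read.table(schedule_path, header = TRUE,
                             sep = sniff_sep(schedule_path),
                             stringsAsFactors = FALSE)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(sched))) {
    stop("schedule must have columns ", paste(need, collapse = ", "))
  }
  duration <- ncol(X) / rate
  if (any(sched$start_s < 0) || any(sched$end_s > duration + 1e-9)) {
    stop("schedule interval outside the recording (duration ",
         format(duration), " s)")
  }
  if (any(sched$end_s <= sched$start_s)) {
    stop("schedule intervals must satisfy start_s < end_s")
  }
  o <- order(sched$start_s)
  so <- sched[o, ]
  if (any(utils::head(so$end_s, -1L) > utils::tail(so$start_s, -1L) + 1e-9)) {
    stop("overlapping schedule intervals")
  }
  lapply(seq_len(nrow(sched)), function(i) {
    i0 <- round(sched$start_s[i] * rate) + 1L
    i1 <- round(sched$end_s[i] * rate)
    recording_segment(X[, i0:i1, drop = FALSE], rate, sched$label[i],
                      start_time = sched$start_s[i])
  })
}

#' Write a recording (and schedule) generated by [make_recording()]
#'
#' @param recording list with `segments` and `schedule` as returned by
#'   [make_recording()].
#' @param path recording output file (rows = samples, columns =
#'   channels).
#' @param schedule_path schedule sidecar output file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, schedule_path) {
  X <- t(do.call(cbind, lapply(recording$segments, `[[`, "samples")))
  fmt <- matrix(sprintf("%.17g", X), nrow = nrow(X),
                dimnames = list(NULL, paste0("ch", seq_len(ncol(X)))))
  utils::write.table(fmt, path, sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(recording$schedule, schedule_path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a full pipeline configuration
#'
#' @param input recording file, or a list of [recording_segment()]s.
#' @param schedule schedule sidecar path (required when `input` is a
#'   file).
#' @param rate sampling rate in Hz (required when `input` is a file).
#' @param out_dir output directory; created if missing. `NULL` disables
#'   file output.
#' @param window,step,onset_skip windowing parameters in seconds
#'   (defaults 20, 5, 0.2).
#' @param n_permutations,seed,comparison_mode,scheme,block_length passed
#'   to [permutation_config()].
#' @param make_plots write trajectory and attractor figures (default
#'   `TRUE` when `out_dir` is set).
#' @param log_level `"info"` prints the proximity matrix and observed
#'   discrimination values; `"quiet"` suppresses messages.
#' @return a list of class `mcs_run_config`.
#' @export
run_config <- function(input, schedule = NULL, rate = NULL, out_dir = NULL,
                       window = 20, step = 5, onset_skip = 0.2,
                       n_permutations = 10000L, seed = NULL,
                       comparison_mode = "add_one_leq",
                       scheme = "full_shuffle", block_length = NULL,
                       make_plots = !is.null(out_dir),
                       log_level = c("info", "quiet")) {
  structure(
    list(input = input, schedule = schedule, rate = rate,
         out_dir = out_dir, window = window, step = step,
         onset_skip = onset_skip,
         permutation = permutation_config(
           n_permutations = n_permutations, seed = seed,
           comparison_mode = comparison_mode, scheme = scheme,
           block_length = block_length),
         make_plots = make_plots,
         log_level = match.arg(log_level)),
    class = "mcs_run_config")
}

# serializable view of a run configuration (for the provenance echo)
config_as_list <- function(config) {
  list(schema_version = 1L,
       input = if (is.character(config$input)) config$input else "<in-memory>",
       schedule = config$schedule, rate = config$rate,
       window = config$window, step = config$step,
       onset_skip = config$onset_skip,
       n_permutations = config$permutation$n_permutations,
       seed = config$permutation$seed,
       comparison_mode = config$permutation$comparison_mode,
       scheme = config$permutation$scheme,
       block_length = config$permutation$block_length,
       make_plots = config$make_plots)
}

#' Run the full analysis pipeline
#'
#' Preprocesses a multichannel recording into labeled state vectors
#' (onset exclusion, sliding-window RMS, across-channel z-score), builds
#' the labeled point set, runs the global and all pairwise permutation
#' tests, and (optionally) writes figures, the point set, the proximity
#' matrix, a machine-readable JSON report and an echo of the exact
#' configuration used into the output directory. Every random draw is
#' governed by the configuration seed, and the statistics are identical
#' whether or not figures are produced.
#'
#' @param config an [run_config()] object.
#' @return the report: a list with elements `M`, `L`, `windows_per_segment`,
#'   `counts`, `proximity`, `global` (delta0, p, ...), `pairs` (data
#'   frame: pair, delta0, p), `pvalue_matrix`, `n_permutations`, `mode`,
#'   `seed`. Invisibly.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "mcs_run_config"))
  say <- function(...) {
    if (config$log_level == "info") message(...)
  }
  segments <- if (is.character(config$input)) {
    read_recording(config$input, config$rate, config$schedule)
  } else config$input

  series <- lapply(segments, function(seg) {
    seg <- exclude_onset(seg, config$onset_skip)
    zscore_states(sliding_rms(seg, config$window, config$step))
  })
  points <- build_pointset(series)
  W <- vapply(series, function(s) nrow(s$vectors), integer(1))
  say("point set: M = ", nrow(points$coordinates), ", L = ",
      length(points$label_order), "; windows per segment: ",
      paste(W, collapse = ", "))

  prox <- proximity_matrix(pairwise_distances(points), points$labels,
                           points$label_order)
  if (config$log_level == "info") {
    message("proximity matrix:")
    message(paste(utils::capture.output(print(unclass(prox))),
                  collapse = "\n"))
  }
  global <- permutation_test_global(points, config$permutation)
  say("global Delta_0 = ", format(global$delta_observed),
      ", p = ", format(global$p_value))
  pmat <- pairwise_pvalue_matrix(points, config$permutation)
  pair_res <- attr(pmat, "results")
  pairs_df <- data.frame(
    pair = names(pair_res),
    delta0 = vapply(pair_res, `[[`, numeric(1), "delta_observed"),
    p = vapply(pair_res, `[[`, numeric(1), "p_value"),
    row.names = NULL)
  for (i in seq_len(nrow(pairs_df))) {
    say("pair ", pairs_df$pair[i], ": Delta_0 = ",
        format(pairs_df$delta0[i]), ", p = ", format(pairs_df$p[i]))
  }

  report <- list(
    M = nrow(points$coordinates),
    L = length(points$label_order),
    windows_per_segment = W,
    counts = as.list(stats::setNames(label_counts(points),
                                     points$label_order)),
    proximity = unclass(prox),
    global = list(delta0 = global$delta_observed, p = global$p_value),
    pairs = pairs_df,
    pvalue_matrix = unclass(pmat),
    n_permutations = config$permutation$n_permutations,
    mode = config$permutation$comparison_mode,
    seed = config$permutation$seed)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(config_as_list(config),
                     file.path(config$out_dir, "config.yaml"))
    write_pointset(points, file.path(config$out_dir, "points.csv"))
    write_labeled_matrix(prox, file.path(config$out_dir, "proximity.csv"))
    rep_json <- report
    rep_json$proximity <- as.data.frame(unclass(prox))
    rep_json$pvalue_matrix <- as.data.frame(unclass(pmat))
    attr(rep_json$pvalue_matrix, "results") <- NULL
    jsonlite::write_json(rep_json,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (config$make_plots) {
      emb <- classical_mds(pairwise_distances(points), 2L)
      plot_state_trajectory(emb, points$labels,
                            file = file.path(config$out_dir,
                                             "trajectory.svg"))
      plot_attractors(embed_centroids(prox),
                      file = file.path(config$out_dir, "attractors.svg"))
    }
  }
  invisible(report)
}
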