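#' Assign a new point to its most probable cluster
#'
#' The query point is tentatively added to each cluster in turn and the
#' global discrimination value (sum of pairwise discrimination values
#' over all label pairs, see [global_discrimination()]) is recomputed for
#' every tentative assignment. The most probable cluster is the one whose
#' assignment minimizes the global discrimination value: adding the point
#' to the cluster it belongs to keeps the configuration compact, whereas
#' adding it to a wrong cluster inflates that cluster's mean intra-
#' distance.
#'
#' The update is incremental: the reference block sums are computed once,
#' and each tentative assignment only adds the distances from the query
#' to the reference points. The result equals a full recomputation of the
#' global discrimination value on the augmented point set (to numerical
#' round-off). The reference set itself is never modified.
#'
#' Ties are broken in favour of the earlier label in the reference's
#' `label_order`, with a warning.
#'
#' @param x numeric vector with the reference set's dimensionality.
#' @param reference an [mcs_pointset()] with at least 2 labels and at
#'   least 2 points per label.
#' @return an object of class `mcs_assignment`: `predicted_label`,
#'   `delta_per_assignment` (named, one global discrimination value per
#'   candidate label) and `margin` (second-best minus best, `>= 0`).
#' @export
assign_point <- function(x, reference) {
  stats <- reference_block_stats(reference)
  res <- assign_one(as.numeric(x), stats)
  if (res$tie) {
    warning("tie between labels ", paste(res$tied, collapse = ", "),
            "; resolved by canonical label order")
  }
  structure(res[c("predicted_label", "delta_per_assignment", "margin")],
            class = "mcs_assignment")
}

#' @export
print.mcs_assignment <- function(x, ...) {
  cat("Assigned to cluster '", x$predicted_label, "' (margin ",
      format(x$margin), ")\n", sep = "")
  print(x$delta_per_assignment)
  invisible(x)
}

#' Assign many points to clusters
#'
#' Vectorized form of [assign_point()]: the reference block sums are
#' computed once and reused for every query row.
#'
#' @param X numeric matrix of query points (rows).
#' @param reference an [mcs_pointset()].
#' @param warn_ties emit a warning for tied assignments (default `TRUE`).
#' @return a data frame with one row per query: `predicted_label`,
#'   `margin`, and one `delta_<label>` column per candidate label.
#' @export
assign_points <- function(X, reference, warn_ties = TRUE) {
  X <- as.matrix(X)
  stats <- reference_block_stats(reference)
  rows <- lapply(seq_len(nrow(X)), function(i) assign_one(X[i, ], stats))
  ties <- which(vapply(rows, `[[`, logical(1), "tie"))
  if (warn_ties && length(ties)) {
    warning("tied assignment for query row(s) ",
            paste(ties, collapse = ", "),
            "; resolved by canonical label order")
  }
  deltas <- do.call(rbind, lapply(rows, `[[`, "delta_per_assignment"))
  colnames(deltas) <- paste0("delta_", stats$labels)
  data.frame(
    predicted_label = vapply(rows, `[[`, character(1), "predicted_label"),
    margin = vapply(rows, `[[`, numeric(1), "margin"),
    deltas)
}

# Precompute per-label counts, unordered within-cluster distance sums and
# one-direction cross-cluster sums of the reference set.
reference_block_stats <- function(reference) {
  stopifnot(inherits(reference, "mcs_pointset"))
  check_testable(reference)
  labs <- reference$label_order
  L <- length(labs)
  f <- factor(reference$labels, levels = labs)
  li <- as.integer(f)
  n <- as.integer(table(f))
  D <- pairwise_distances(reference)
  B <- rowsum(t(rowsum(D, li)), li)  # B[a,b]: sum over pairs (i in a, j in b)
  W <- diag(B) / 2                   # unordered within-cluster sums
  Cx <- B; diag(Cx) <- 0             # cross sums, each unordered pair once
  list(coords = reference$coordinates, li = li, labels = labs, L = L,
       n = n, within = W, cross = Cx)
}

# Delta_global for the reference set with x tentatively added to each
# cluster, via incremental update of the block sums.
assign_one <- function(x, stats) {
  if (length(x) != ncol(stats$coords)) {
    stop("query point has dimension ", length(x), " but the reference is ",
         ncol(stats$coords), "-dimensional")
  }
  dvec <- sqrt(colSums((t(stats$coords) - x)^2))
  s <- as.numeric(rowsum(dvec, stats$li))  # distance sums to each cluster
  L <- stats$L
  deltas <- vapply(seq_len(L), function(i) {
    n <- stats$n
    W <- stats$within
    Cx <- stats$cross
    W[i] <- W[i] + s[i]
    Cx[i, ] <- Cx[i, ] + s
    Cx[i, i] <- 0
    Cx[, i] <- Cx[i, ]
    n[i] <- n[i] + 1L
    P <- Cx / tcrossprod(n)
    diag(P) <- W / (n * (n - 1) / 2)
    delta_global_from_blocks(P)
  }, numeric(1))
  names(deltas) <- stats$labels
  ord <- order(deltas)
  best <- ord[1L]
  margin <- if (L > 1L) deltas[ord[2L]] - deltas[best] else 0
  tied <- stats$labels[deltas == deltas[best]]
  list(predicted_label = stats$labels[best],
       delta_per_assignment = deltas,
       margin = unname(margin),
       tie = length(tied) > 1L,
       tied = tied)
}
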