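#' Construct a labeled point set
#'
#' A labeled point set holds `M` observations in `n`-dimensional space,
#' each carrying one of `L` condition labels. It is the common input of
#' the cluster statistics: each row is one state vector (or any other
#' feature vector) and the label names the experimental condition under
#' which it was observed.
#'
#' The constructor validates coordinate finiteness and length agreement.
#' Requirements specific to the statistics (at least two labels, at least
#' two observations per label, so that every cluster has at least one
#' within-cluster pair) are enforced by the statistical functions
#' themselves: a single-label point set is a legal input for
#' visualization even though it cannot be tested.
#'
#' @param coordinates numeric matrix, `M` rows (observations) by `n`
#'   columns (dimensions). Row order is observation time order.
#' @param labels character vector (or factor) of length `M` giving the
#'   condition label of each observation.
#' @param label_order canonical ordering of the distinct labels; defaults
#'   to their order of first appearance. Proximity matrices, p-value
#'   matrices and tie-breaking all follow this ordering.
#' @param origin optional integer vector of length `M` recording the
#'   segment of origin of each observation (filled in by
#'   [build_pointset()]).
#' @param window_centers optional numeric vector of length `M` of
#'   observation times in seconds.
#' @return an object of class `mcs_pointset`.
#' @seealso [proximity_matrix()], [permutation_test_pair()],
#'   [read_pointset()]
#' @examples
#' ps <- mcs_pointset(rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2)),
#'                    labels = c("A", "A", "B", "B"))
#' ps
#' @export
mcs_pointset <- function(coordinates, labels, label_order = NULL,
                         origin = NULL, window_centers = NULL) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  labels <- as.character(labels)
  if (nrow(coordinates) != length(labels)) {
    stop("number of coordinate rows (", nrow(coordinates),
         ") does not match number of labels (", length(labels), ")")
  }
  bad <- which(!apply(is.finite(coordinates), 1L, all))
  if (length(bad)) {
    stop("non-finite coordinate in row(s) ", paste(bad, collapse = ", "))
  }
  if (is.null(label_order)) {
    label_order <- unique(labels)
  } else {
    label_order <- as.character(label_order)
    if (!all(labels %in% label_order)) {
      stop("labels found that are absent from 'label_order': ",
           paste(setdiff(labels, label_order), collapse = ", "))
    }
    label_order <- label_order[label_order %in% labels]
  }
  if (is.null(colnames(coordinates))) {
    colnames(coordinates) <- paste0("d", seq_len(ncol(coordinates)))
  }
  structure(
    list(coordinates = coordinates, labels = labels,
         label_order = label_order, origin = origin,
         window_centers = window_centers),
    class = "mcs_pointset")
}

#' @export
print.mcs_pointset <- function(x, ...) {
  cnt <- table(factor(x$labels, levels = x$label_order))
  cat("Labeled point set: M =", nrow(x$coordinates),
      "points in", ncol(x$coordinates), "dimensions, L =",
      length(x$label_order), "labels\n")
  print(cnt)
  invisible(x)
}

#' @export
dim.mcs_pointset <- function(x) dim(x$coordinates)

# number of points per label, in label_order
label_counts <- function(points) {
  as.integer(table(factor(points$labels, levels = points$label_order)))
}

# checks the point set can enter the cluster statistics
check_testable <- function(points, labels = points$label_order) {
  if (length(labels) < 2L) {
    stop("at least 2 distinct labels are required for cluster statistics")
  }
  cnt <- table(factor(points$labels, levels = labels))
  if (any(cnt < 2L)) {
    stop("degenerate cluster: label(s) ",
         paste(names(cnt)[cnt < 2L], collapse = ", "),
         " have fewer than 2 points (intra-cluster mean distance needs ",
         "at least one within-cluster pair)")
  }
  invisible(TRUE)
}

#' Subset a labeled point set to a set of labels
#'
#' @param points an [mcs_pointset()].
#' @param labels labels to keep (in `label_order`).
#' @return an `mcs_pointset` containing only the selected observations,
#'   in their original time order.
#' @export
subset_labels <- function(points, labels) {
  stopifnot(inherits(points, "mcs_pointset"))
  labels <- as.character(labels)
  missing_lab <- setdiff(labels, points$label_order)
  if (length(missing_lab)) {
    stop("unknown label(s): ", paste(missing_lab, collapse = ", "))
  }
  keep <- points$labels %in% labels
  mcs_pointset(points$coordinates[keep, , drop = FALSE],
               points$labels[keep],
               label_order = points$label_order[points$label_order %in% labels],
               origin = points$origin[keep],
               window_centers = points$window_centers[keep])
}
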