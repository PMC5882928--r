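#' Classical (Torgerson) metric multidimensional scaling
#'
#' Embeds a distance matrix into `target_dim` dimensions by double
#' centering and eigendecomposition, keeping the `target_dim` largest
#' non-negative eigenvalues (negative eigenvalues are truncated to zero
#' and their axes padded with zero coordinates). Classical scaling is
#' deterministic — there is no random initialization — and reproduces
#' planar configurations exactly. MDS is used for visualization only;
#' all statistics operate on the full-dimensional distances and are
#' independent of the embedding.
#'
#' Reflection indeterminacy is removed by a fixed alignment convention:
#' axes are ordered by decreasing eigenvalue and the sign of each axis is
#' chosen so that its largest-magnitude coordinate is positive.
#'
#' @param dist a distance matrix (or `dist` object), e.g. from
#'   [pairwise_distances()].
#' @param target_dim embedding dimension (default 2).
#' @return an object of class `mcs_embedding`: list with `coordinates`
#'   (`M x target_dim`, column-centered, arbitrary units), `eigenvalues`
#'   (all `M` eigenvalues of the doubly centered Gram matrix), `stress`
#'   (residual distance distortion,
#'   `sqrt(sum((d - dhat)^2) / sum(d^2))`; 0 when all distances are
#'   reproduced) and `alignment`.
#' @export
classical_mds <- function(dist, target_dim = 2L) {
  D <- as.matrix(dist)
  M <- nrow(D)
  if (target_dim < 1L) stop("'target_dim' must be at least 1")
  if (M < target_dim + 1L) {
    stop("need at least target_dim + 1 = ", target_dim + 1L,
         " points, got ", M)
  }
  sol <- stats::cmdscale(D, k = target_dim, eig = TRUE)
  pts <- sol$points
  if (ncol(pts) < target_dim) {   # fewer positive eigenvalues than axes
    pts <- cbind(pts, matrix(0, M, target_dim - ncol(pts)))
  }
  # sign convention: largest-magnitude coordinate on each axis positive
  for (k in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, k]))
    if (pts[i, k] < 0) pts[, k] <- -pts[, k]
  }
  dhat <- as.matrix(stats::dist(pts))
  denom <- sum(D^2)
  stress <- if (denom > 0) sqrt(sum((D - dhat)^2) / denom) else 0
  structure(
    list(coordinates = pts, eigenvalues = sol$eig, stress = stress,
         alignment = paste("axes by decreasing eigenvalue;",
                           "largest-magnitude coordinate positive")),
    class = "mcs_embedding")
}

#' @export
print.mcs_embedding <- function(x, ...) {
  cat("Classical MDS embedding:", nrow(x$coordinates), "points in",
      ncol(x$coordinates), "dimensions; stress =", format(x$stress), "\n")
  invisible(x)
}

#' Embed cluster centroids from a proximity matrix
#'
#' Projects the clusters' relative positions onto the plane by classical
#' MDS of the mean inter-cluster distances (the proximity matrix with its
#' diagonal replaced by zero). Together with the mean intra-cluster
#' distances — drawn as disks of that diameter around the projected
#' centroids — this gives the abstracted "attractor basin" view of a
#' spatial configuration: disks that do not overlap correspond to a
#' negative discrimination value for that pair.
#'
#' @param prox a proximity matrix from [proximity_matrix()].
#' @return an object of class `mcs_attractors`: `centroid_xy` (`L x 2`),
#'   `diameters` (the proximity diagonal, i.e. mean intra-cluster
#'   distances), `labels`, `stress`. With `L = 2` the layout is a line
#'   padded with a zero second coordinate.
#' @export
embed_centroids <- function(prox) {
  L <- nrow(prox)
  if (L < 2L) stop("at least 2 clusters are required")
  D0 <- unclass(prox)
  diameters <- diag(D0)
  diag(D0) <- 0
  emb <- classical_mds(D0, target_dim = min(2L, L - 1L))
  xy <- emb$coordinates
  if (ncol(xy) < 2L) xy <- cbind(xy, 0)
  colnames(xy) <- c("x", "y")
  rownames(xy) <- rownames(prox)
  structure(
    list(centroid_xy = xy,
         diameters = stats::setNames(diameters, rownames(prox)),
         labels = rownames(prox), stress = emb$stress),
    class = "mcs_attractors")
}

#' @export
print.mcs_attractors <- function(x, ...) {
  cat("Attractor summary for", length(x$labels), "clusters\n")
  print(cbind(x$centroid_xy, diameter = x$diameters))
  invisible(x)
}

#' Plot a state-space trajectory with attractor basins
#'
#' Draws the embedded state vectors colored by condition, connected in
#' time order within each contiguous condition run (the trajectory), and
#' overlays per-condition centroid disks whose diameters equal the mean
#' intra-cluster distance in the embedding. Axes are in arbitrary units,
#' as the embedding is defined only up to rigid motion.
#'
#' @param embedding an `mcs_embedding` from [classical_mds()] (2-D).
#' @param labels condition label per embedded point.
#' @param time_order integer ordering of the points in time (default:
#'   row order).
#' @param file output path; the graphics device is chosen from the
#'   extension (`.svg`, `.png` or `.pdf`). `NULL` draws on the current
#'   device.
#' @param main plot title.
#' @param width,height device size in inches.
#' @return the path (or `NULL`), invisibly.
#' @export
plot_state_trajectory <- function(embedding, labels,
                                  time_order = seq_along(labels),
                                  file = NULL, main = "State-space trajectory",
                                  width = 7, height = 7) {
  stopifnot(inherits(embedding, "mcs_embedding"))
  xy <- embedding$coordinates[, 1:2, drop = FALSE]
  labels <- as.character(labels)
  if (nrow(xy) != length(labels)) {
    stop("embedding has ", nrow(xy), " points but ", length(labels),
         " labels were given")
  }
  if (length(time_order) != length(labels)) {
    stop("'time_order' length does not match the number of points")
  }
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
      svg = grDevices::svg(file, width = width, height = height),
      png = grDevices::png(file, width = width * 96, height = height * 96,
                           res = 96),
      pdf = grDevices::pdf(file, width = width, height = height),
      stop("unsupported figure format: .", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  labs_present <- unique(labels[!is.na(labels)])
  cols <- stats::setNames(grDevices::hcl.colors(max(3L, length(labs_present)),
                                                "Dark 3")[seq_along(labs_present)],
                          labs_present)
  ord <- order(time_order)
  xo <- xy[ord, , drop = FALSE]
  lo <- labels[ord]
  graphics::plot(xy, type = "n", asp = 1, xlab = "MDS 1 (a.u.)",
                 ylab = "MDS 2 (a.u.)", main = main)
  # one polyline per contiguous condition run
  runs <- rle(lo)
  idx_end <- cumsum(runs$lengths)
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  for (k in seq_along(runs$values)) {
    seg <- idx_start[k]:idx_end[k]
    graphics::lines(xo[seg, 1L], xo[seg, 2L],
                    col = cols[runs$values[k]], lwd = 1)
  }
  graphics::points(xy, pch = 19, cex = 0.6, col = cols[labels])
  # centroid disks: diameter = mean intra-cluster distance in the embedding
  for (lab in labs_present) {
    pts <- xy[labels == lab, , drop = FALSE]
    if (nrow(pts) >= 2L) {
      ctr <- colMeans(pts)
      diam <- mean(stats::dist(pts))
      graphics::symbols(ctr[1L], ctr[2L], circles = diam / 2,
                        inches = FALSE, add = TRUE, fg = cols[lab],
                        bg = grDevices::adjustcolor(cols[lab], alpha.f = 0.25))
    }
  }
  graphics::legend("topright", legend = labs_present, col = cols[labs_present],
                   pch = 19, bty = "n")
  invisible(file)
}

#' Plot the attractor-basin summary
#'
#' Draws each cluster as a disk at its embedded centroid with diameter
#' equal to its mean intra-cluster distance.
#'
#' @param attractors an `mcs_attractors` from [embed_centroids()].
#' @inheritParams plot_state_trajectory
#' @return the path (or `NULL`), invisibly.
#' @export
plot_attractors <- function(attractors, file = NULL,
                            main = "Attractor basins",
                            width = 7, height = 7) {
  stopifnot(inherits(attractors, "mcs_attractors"))
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
      svg = grDevices::svg(file, width = width, height = height),
      png = grDevices::png(file, width = width * 96, height = height * 96,
                           res = 96),
      pdf = grDevices::pdf(file, width = width, height = height),
      stop("unsupported figure format: .", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  xy <- attractors$centroid_xy
  r <- attractors$diameters / 2
  cols <- stats::setNames(
    grDevices::hcl.colors(max(3L, length(attractors$labels)),
                          "Dark 3")[seq_along(attractors$labels)],
    attractors$labels)
  lim <- range(c(xy[, 1] - r, xy[, 1] + r, xy[, 2] - r, xy[, 2] + r))
  graphics::plot(NA, xlim = lim, ylim = lim, asp = 1,
                 xlab = "MDS 1 (a.u.)", ylab = "MDS 2 (a.u.)", main = main)
  graphics::symbols(xy[, 1], xy[, 2], circles = pmax(r, 1e-9),
                    inches = FALSE, add = TRUE, fg = cols,
                    bg = grDevices::adjustcolor(cols, alpha.f = 0.25))
  graphics::text(xy[, 1], xy[, 2], attractors$labels)
  invisible(file)
}
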