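# Small fixtures and independent brute-force oracles used across tests.

# two 2-point rectangles: A = {(0,0),(0,2)}, B = {(10,0),(10,2)}
two_rect_pointset <- function() {
  mcs_pointset(rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2)),
               c("A", "A", "B", "B"))
}

# collinear points at 0, 1, 10, 11 labeled A A B B
line_pointset <- function() {
  mcs_pointset(cbind(c(0, 1, 10, 11)), c("A", "A", "B", "B"))
}

# brute-force proximity matrix: explicit double loop over all point pairs
brute_proximity <- function(coords, labels, label_order = unique(labels)) {
  L <- length(label_order)
  sums <- matrix(0, L, L, dimnames = list(label_order, label_order))
  cnts <- matrix(0, L, L)
  M <- nrow(coords)
  for (i in seq_len(M - 1L)) {
    for (j in seq((i + 1L), M)) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      a <- match(labels[i], label_order)
      b <- match(labels[j], label_order)
      sums[a, b] <- sums[a, b] + d
      cnts[a, b] <- cnts[a, b] + 1
      if (a != b) {
        sums[b, a] <- sums[b, a] + d
        cnts[b, a] <- cnts[b, a] + 1
      }
    }
  }
  sums / cnts
}

# brute-force global discrimination value straight from coordinates
brute_global_delta <- function(coords, labels, label_order = unique(labels)) {
  P <- brute_proximity(coords, labels, label_order)
  L <- nrow(P)
  tot <- 0
  for (a in seq_len(L - 1L)) {
    for (b in seq((a + 1L), L)) {
      tot <- tot + P[a, a] + P[b, b] - 2 * P[a, b]
    }
  }
  tot
}

# exhaustive two-cluster permutation null: enumerate every count-preserving
# labeling and compute Delta through the brute-force proximity path
brute_pair_null <- function(coords, labels, a, b) {
  keep <- labels %in% c(a, b)
  coords <- coords[keep, , drop = FALSE]
  labels <- labels[keep]
  m <- nrow(coords)
  nA <- sum(labels == a)
  combos <- utils::combn(m, nA)
  apply(combos, 2L, function(idx) {
    lab <- rep(b, m)
    lab[idx] <- a
    P <- brute_proximity(coords, lab, c(a, b))
    P[1, 1] + P[2, 2] - 2 * P[1, 2]
  })
}

# random rigid motion: orthogonal matrix (QR of a Gaussian) plus shift
apply_rigid_motion <- function(coords, seed = 1) {
  set.seed(seed)
  n <- ncol(coords)
  Q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  shift <- rnorm(n, sd = 5)
  sweep(coords %*% Q, 2L, shift, "+")
}

# Procrustes residual after optimal translation/rotation/reflection,
# computed from first principles (independent of any package MDS code)
procrustes_residual <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Y, X))
  R <- s$u %*% t(s$v)
  sqrt(sum((X - Y %*% R)^2))
}
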