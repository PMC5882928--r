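test_that("pairwise distances match hand-computed geometry", {
  d <- pairwise_distances(rbind(c(0, 0), c(3, 4)))
  expect_equal(d[1, 2], 5)
  expect_equal(d[2, 1], 5)
  expect_equal(diag(d), c(0, 0), ignore_attr = TRUE)

  same <- pairwise_distances(matrix(2, nrow = 3, ncol = 4))
  expect_true(all(same == 0))

  ps <- two_rect_pointset()
  d <- pairwise_distances(ps)
  cross <- d[ps$labels == "A", ps$labels == "B"]
  expect_equal(sort(as.numeric(cross)), sort(c(10, sqrt(104), sqrt(104), 10)))
})

test_that("distance matrix is a metric on random instances", {
  set.seed(42)
  coords <- matrix(rnorm(8 * 3), 8, 3)
  d <- pairwise_distances(coords)
  expect_equal(d, t(d))
  expect_true(all(d >= 0))
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("non-finite coordinates are rejected with the offending row", {
  expect_error(pairwise_distances(rbind(c(0, 0), c(NaN, 1), c(2, 2))),
               "row\\(s\\) 2")
  expect_error(mcs_pointset(rbind(c(0, 0), c(1, 1), c(Inf, 0)), c("A", "A", "B")),
               "row\\(s\\) 3")
})

test_that("proximity matrix holds block means of intra and cross distances", {
  ps <- two_rect_pointset()
  prox <- proximity_matrix(pairwise_distances(ps), ps$labels)
  expect_equal(prox["A", "A"], 2)
  expect_equal(prox["B", "B"], 2)
  expect_equal(prox["A", "B"], (10 + sqrt(104) + sqrt(104) + 10) / 4)
  expect_equal(prox["A", "B"], prox["B", "A"])

  # both clusters on the same two points: cross pairs {0, 2, 2, 0}
  ov <- mcs_pointset(rbind(c(0, 0), c(0, 2), c(0, 0), c(0, 2)),
                     c("A", "A", "B", "B"))
  pov <- proximity_matrix(pairwise_distances(ov), ov$labels)
  expect_equal(pov["A", "A"], 2)
  expect_equal(pov["B", "B"], 2)
  expect_equal(pov["A", "B"], 1)

  ident <- mcs_pointset(matrix(1, 4, 3), c("A", "A", "B", "B"))
  expect_true(all(proximity_matrix(pairwise_distances(ident),
                                   ident$labels) == 0))
})

test_that("proximity matrix agrees with a brute-force double loop", {
  set.seed(7)
  for (rep in 1:5) {
    M <- sample(10:50, 1)
    n <- sample(2:5, 1)
    L <- sample(2:4, 1)
    labs <- sample(c(rep(LETTERS[1:L], 2),
                     sample(LETTERS[1:L], M - 2 * L, replace = TRUE)))
    coords <- matrix(rnorm(M * n), M, n)
    prox <- proximity_matrix(pairwise_distances(coords), labs, LETTERS[1:L])
    expect_equal(unclass(prox), brute_proximity(coords, labs, LETTERS[1:L]),
                 tolerance = 1e-12)
  }
})

test_that("degenerate clusters are rejected", {
  expect_error(proximity_matrix(pairwise_distances(rbind(0, 1, 2)),
                                c("A", "A", "B")),
               "degenerate cluster")
})

test_that("discrimination value follows its defining formula and sign logic", {
  ps <- two_rect_pointset()
  prox <- proximity_matrix(pairwise_distances(ps), ps$labels)
  expect_equal(discrimination_value(prox, "A", "B"),
               2 + 2 - 2 * (20 + 2 * sqrt(104)) / 4)
  expect_lt(discrimination_value(prox, "A", "B"), 0)   # disjoint
  expect_equal(discrimination_value(prox, "A", "B"),
               discrimination_value(prox, "B", "A"))

  ov <- mcs_pointset(rbind(c(0, 0), c(0, 2), c(0, 0), c(0, 2)),
                     c("A", "A", "B", "B"))
  pov <- proximity_matrix(pairwise_distances(ov), ov$labels)
  expect_equal(discrimination_value(pov, "A", "B"), 2)  # overlapping
  ident <- mcs_pointset(matrix(1, 4, 3), c("A", "A", "B", "B"))
  expect_identical(
    discrimination_value(proximity_matrix(pairwise_distances(ident),
                                          ident$labels), "A", "B"), 0)
  expect_error(discrimination_value(prox, "A", "A"), "distinct")
})

test_that("global discrimination reduces to the pairwise value at L = 2 and
           sums pairwise values otherwise", {
  ps <- two_rect_pointset()
  prox <- proximity_matrix(pairwise_distances(ps), ps$labels)
  expect_equal(global_discrimination(prox),
               discrimination_value(prox, "A", "B"))

  coords <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2), c(0, 100), c(0, 102))
  labs <- c("A", "A", "B", "B", "C", "C")
  p3 <- proximity_matrix(pairwise_distances(coords), labs)
  expect_equal(global_discrimination(p3),
               discrimination_value(p3, "A", "B") +
                 discrimination_value(p3, "A", "C") +
                 discrimination_value(p3, "B", "C"))
  expect_equal(global_discrimination(p3), brute_global_delta(coords, labs))

  ident3 <- matrix(1, 6, 2)
  expect_equal(global_discrimination(
    proximity_matrix(pairwise_distances(ident3), labs)), 0)
})

test_that("discrimination value is rigid-motion invariant and scales linearly", {
  set.seed(11)
  coords <- matrix(rnorm(30 * 4), 30, 4)
  labs <- rep(c("A", "B", "C"), each = 10)
  delta <- function(xy) {
    global_discrimination(proximity_matrix(pairwise_distances(xy), labs))
  }
  d0 <- delta(coords)
  expect_equal(delta(apply_rigid_motion(coords, seed = 3)), d0,
               tolerance = 1e-10)
  refl <- coords; refl[, 1] <- -refl[, 1]
  expect_equal(delta(refl), d0, tolerance = 1e-12)
  for (s in c(0.5, 2, 7.3)) {
    expect_equal(delta(coords * s), s * d0, tolerance = 1e-10)
  }
})

test_that("moving disjoint clusters apart strictly decreases Delta", {
  set.seed(13)
  base <- matrix(rnorm(40 * 3, sd = 0.5), 40, 3)
  labs <- rep(c("A", "B"), each = 20)
  deltas <- sapply(c(3, 5, 8, 12), function(sep) {
    xy <- base
    xy[labs == "B", 1] <- xy[labs == "B", 1] + sep
    prox <- proximity_matrix(pairwise_distances(xy), labs)
    discrimination_value(prox, "A", "B")
  })
  expect_true(all(diff(deltas) < 0))
  expect_true(all(deltas < 0))
})
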