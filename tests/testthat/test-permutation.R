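test_that("permute_labels preserves the label multiset and is uniform", {
  labs <- c("A", "A", "B", "B")
  set.seed(1)
  draws <- replicate(60000, paste(permute_labels(labs), collapse = ""))
  expect_true(all(sort(table(strsplit(names(table(draws))[1], "")[[1]])) ==
                    c(2, 2)))
  tab <- table(draws)
  expect_length(tab, 6L)  # all 6 count-preserving arrangements occur
  chi <- sum((tab - 10000)^2 / 10000)
  expect_lt(chi, qchisq(0.999, df = 5))

  expect_identical(permute_labels("A"), "A")
})

test_that("block shuffle moves contiguous blocks and preserves counts", {
  labs <- rep(c("A", "B", "C"), each = 4)
  set.seed(2)
  for (i in 1:20) {
    out <- permute_labels(labs, scheme = "block_shuffle", block_length = 4)
    expect_identical(sort(out), sort(labs))
    # blocks of 4 move as units: each aligned block stays homogeneous
    expect_true(all(apply(matrix(out, nrow = 4), 2,
                          function(b) length(unique(b)) == 1L)))
  }
  # block length equal to M: the sequence moves as one unit
  expect_identical(permute_labels(labs, "block_shuffle", length(labs)), labs)
  expect_error(permute_labels(labs, "block_shuffle", 13), "exceeds")
  expect_error(permutation_config(scheme = "block_shuffle"), "block_length")
})

test_that("the collinear 4-point example reproduces its exhaustive null", {
  ps <- line_pointset()
  res <- permutation_test_pair(ps, "A", "B", permutation_config(seed = 1))
  expect_true(res$exhaustive)
  expect_equal(res$delta_observed, -18)
  expect_equal(sort(res$delta_null), c(-18, -18, 9, 9, 9, 9))
  expect_equal(res$p_value, 2 / 6)

  strict <- permutation_test_pair(
    ps, "A", "B",
    permutation_config(seed = 1, comparison_mode = "paper_literal_strict"))
  expect_equal(strict$p_value, 0)

  # independent oracle: brute-force enumeration through double-loop means
  oracle <- brute_pair_null(ps$coordinates, ps$labels, "A", "B")
  expect_equal(sort(res$delta_null), sort(oracle))
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration", {
  set.seed(3)
  for (rep in 1:4) {
    m <- sample(6:10, 1)
    nA <- sample(2:(m - 2), 1)
    coords <- matrix(rnorm(m * 3), m, 3)
    labs <- c(rep("A", nA), rep("B", m - nA))
    ps <- mcs_pointset(coords, labs)
    ex <- permutation_test_pair(ps, "A", "B",
                                permutation_config(exhaustive = "always"))
    mc <- permutation_test_pair(
      ps, "A", "B",
      permutation_config(n_permutations = 10000, seed = rep,
                         exhaustive = "never"))
    expect_false(mc$exhaustive)
    expect_true(ex$exhaustive)
    expect_equal(mc$delta_observed, ex$delta_observed)
    expect_lt(abs(mc$p_value - ex$p_value), 0.02)
  }
})

test_that("identical points give a degenerate null with add-one p = 1", {
  ps <- mcs_pointset(matrix(1, 6, 2), rep(c("A", "B"), each = 3))
  res <- permutation_test_global(ps, permutation_config(seed = 1))
  expect_true(all(res$delta_null == 0))
  expect_equal(res$delta_observed, 0)
  expect_equal(res$p_value, 1)
})

test_that("fixed seed gives bit-identical results; null invariant to A/B swap", {
  ps <- make_gaussian_clusters(2, 12, dimension = 4, separation = 1, seed = 5)
  cfg <- permutation_config(n_permutations = 300, seed = 99,
                            exhaustive = "never")
  r1 <- permutation_test_pair(ps, "A", "B", cfg)
  r2 <- permutation_test_pair(ps, "A", "B", cfg)
  expect_identical(r1$delta_null, r2$delta_null)
  expect_identical(r1$p_value, r2$p_value)

  swapped <- mcs_pointset(ps$coordinates,
                          ifelse(ps$labels == "A", "B", "A"),
                          label_order = c("A", "B"))
  r3 <- permutation_test_pair(swapped, "A", "B", cfg)
  expect_equal(r3$delta_null, r1$delta_null)
})

test_that("global test at L = 2 matches the pairwise test", {
  ps <- make_gaussian_clusters(2, 10, dimension = 3, separation = 2, seed = 8)
  cfg <- permutation_config(n_permutations = 250, seed = 17,
                            exhaustive = "never")
  pr <- permutation_test_pair(ps, "A", "B", cfg)
  gl <- permutation_test_global(ps, cfg)
  expect_equal(gl$delta_observed, pr$delta_observed)
  expect_equal(gl$delta_null, pr$delta_null)
  expect_equal(gl$p_value, pr$p_value)

  # exhaustive route: same null distribution up to ordering
  small <- make_gaussian_clusters(2, 4, dimension = 3, separation = 1,
                                  seed = 21)
  pre <- permutation_test_pair(small, "A", "B", permutation_config())
  gle <- permutation_test_global(small, permutation_config())
  expect_true(pre$exhaustive && gle$exhaustive)
  expect_equal(sort(gle$delta_null), sort(pre$delta_null))
  expect_equal(gle$p_value, pre$p_value)
})

test_that("well-separated clusters are detected, overlapping ones are not", {
  sep <- make_gaussian_clusters(3, 40, dimension = 8, separation = 5,
                                seed = 30)
  res <- permutation_test_global(sep, permutation_config(999, seed = 31))
  expect_lt(res$delta_observed, 0)
  expect_equal(res$p_value, 1 / 1000)

  null <- make_gaussian_clusters(3, 40, dimension = 8, separation = 0,
                                 seed = 32)
  resn <- permutation_test_global(null, permutation_config(999, seed = 33))
  expect_gt(resn$p_value, 0.05)
})

test_that("p-values are approximately uniform under an exchangeable null", {
  set.seed(44)
  pvals <- replicate(200, {
    ps <- make_gaussian_clusters(2, 15, dimension = 4, separation = 0)
    permutation_test_pair(ps, "A", "B",
                          permutation_config(199, exhaustive = "never")
    )$p_value
  })
  expect_gt(mean(pvals), 0.42)
  expect_lt(mean(pvals), 0.58)
  expect_lt(mean(pvals <= 0.05), 0.11)
  expect_true(all(pvals >= 1 / 200))  # add-one lower bound
})

test_that("rejection rate is non-decreasing in cluster separation", {
  set.seed(55)
  rates <- sapply(c(0, 1, 2, 5), function(sep) {
    mean(replicate(40, {
      ps <- make_gaussian_clusters(2, 30, dimension = 8, separation = sep)
      permutation_test_pair(ps, "A", "B",
                            permutation_config(199, exhaustive = "never")
      )$p_value <= 0.05
    }))
  })
  expect_true(all(diff(rates) >= -0.05))
  expect_lt(rates[1], 0.15)
  expect_equal(rates[4], 1)
})

test_that("pairwise p-value matrix is symmetric, reproducible and adjustable", {
  ps <- make_gaussian_clusters(3, 20, dimension = 6, separation = 5,
                               seed = 60)
  cfg <- permutation_config(299, seed = 61, exhaustive = "never")
  pm1 <- pairwise_pvalue_matrix(ps, cfg)
  pm2 <- pairwise_pvalue_matrix(ps, cfg)
  expect_identical(unclass(pm1), unclass(pm2))
  expect_equal(pm1, t(pm1), ignore_attr = TRUE)
  expect_true(all(is.na(diag(pm1))))
  expect_true(all(pm1[upper.tri(pm1)] <= 1 / 300 + 1e-12))

  holm <- pairwise_pvalue_matrix(ps, cfg, adjust = "holm")
  expect_true(all(holm[upper.tri(holm)] >= pm1[upper.tri(pm1)]))

  two <- make_gaussian_clusters(2, 10, dimension = 3, separation = 2,
                                seed = 62)
  pm <- pairwise_pvalue_matrix(two, permutation_config(99, seed = 63))
  expect_equal(dim(pm), c(2L, 2L))
  expect_false(is.na(pm[1, 2]))
})

test_that("degenerate inputs raise informative errors", {
  ps <- mcs_pointset(rbind(c(0, 0), c(1, 1), c(2, 2)), c("A", "A", "B"))
  expect_error(permutation_test_pair(ps, "A", "B"), "degenerate cluster")
  expect_error(permutation_test_pair(two_rect_pointset(), "A", "A"),
               "distinct")
})
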