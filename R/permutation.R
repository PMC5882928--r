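#' Configuration for the label-permutation test
#'
#' @param n_permutations number of random relabelings `N` (default
#'   `10^4`). When the number of distinct count-preserving labelings is
#'   at most `n_permutations` (and `exhaustive = "auto"`), the null
#'   distribution is enumerated exhaustively instead of sampled.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#'   A fixed seed makes the result bit-reproducible; the global RNG state
#'   is restored on exit.
#' @param comparison_mode how the p-value is computed from the null
#'   draws. `"add_one_leq"` (default) uses the add-one estimator
#'   `(1 + #\{Delta_i <= Delta_0\}) / (N + 1)`, which is a valid
#'   permutation p-value bounded below by `1/(N+1)`.
#'   `"paper_literal_strict"` is the plain empirical probability
#'   `Pr(X < Delta_0)` of finding, by random relabeling, a strictly more
#'   negative (better) discrimination value; it can return exactly 0.
#' @param scheme `"full_shuffle"` (default) draws uniformly from all
#'   count-preserving relabelings. `"block_shuffle"` permutes contiguous
#'   blocks of `block_length` observations as units; this is the
#'   conservative choice when successive observations are autocorrelated
#'   (e.g. state vectors from overlapping sliding windows), where full
#'   exchangeability does not hold.
#' @param block_length block size (in observations) for
#'   `scheme = "block_shuffle"`.
#' @param exhaustive `"auto"` (enumerate when feasible, see above),
#'   `"never"` (always Monte Carlo), or `"always"` (error if the number
#'   of distinct labelings is too large to enumerate).
#' @return a list of class `mcs_permutation_config`.
#' @export
permutation_config <- function(n_permutations = 10000L, seed = NULL,
                               comparison_mode = c("add_one_leq",
                                                   "paper_literal_strict"),
                               scheme = c("full_shuffle", "block_shuffle"),
                               block_length = NULL,
                               exhaustive = c("auto", "never", "always")) {
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L) {
    stop("'n_permutations' must be a positive integer")
  }
  comparison_mode <- match.arg(comparison_mode)
  scheme <- match.arg(scheme)
  exhaustive <- match.arg(exhaustive)
  if (scheme == "block_shuffle") {
    if (is.null(block_length) || as.integer(block_length) < 1L) {
      stop("'block_length' must be a positive integer for block_shuffle")
    }
    block_length <- as.integer(block_length)
  }
  structure(
    list(n_permutations = n_permutations, seed = seed,
         comparison_mode = comparison_mode, scheme = scheme,
         block_length = block_length, exhaustive = exhaustive),
    class = "mcs_permutation_config")
}

# evaluate expr with the RNG seeded from config (restoring global state)
with_config_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# one random index permutation under the chosen scheme
permute_indices <- function(M, scheme = "full_shuffle", block_length = NULL) {
  if (scheme == "full_shuffle") return(sample.int(M))
  if (block_length > M) {
    stop("'block_length' (", block_length, ") exceeds the number of ",
         "observations (", M, ")")
  }
  blocks <- split(seq_len(M), ceiling(seq_len(M) / block_length))
  unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
}

#' Randomly relabel observations, preserving class sizes
#'
#' Returns a uniformly random rearrangement of the exact multiset of
#' labels. Under `scheme = "block_shuffle"` contiguous blocks of labels
#' move as units (the final partial block, if any, also moves as a unit),
#' which respects serial dependence between neighbouring observations.
#'
#' @param labels label vector.
#' @inheritParams permutation_config
#' @return a permuted label vector with identical class counts.
#' @export
permute_labels <- function(labels, scheme = c("full_shuffle", "block_shuffle"),
                           block_length = NULL) {
  scheme <- match.arg(scheme)
  labels[permute_indices(length(labels), scheme, block_length)]
}

# number of distinct count-preserving labelings, as a double
multiset_count <- function(counts) {
  exp(lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)))
}

# all distinct arrangements of the multiset {1^counts[1], ..., L^counts[L]}
# as rows of an integer matrix; only called for small problems
multiset_permutations <- function(counts) {
  counts <- as.integer(counts)
  M <- sum(counts)
  L <- length(counts)
  total <- round(multiset_count(counts))
  if (total > 250000) {
    stop("exhaustive enumeration infeasible: ", total, " distinct labelings")
  }
  out <- matrix(0L, nrow = total, ncol = M)
  row <- 0L
  cur <- integer(M)
  gen <- function(pos, cnt) {
    if (pos > M) {
      row <<- row + 1L
      out[row, ] <<- cur
      return(invisible(NULL))
    }
    for (l in seq_len(L)) {
      if (cnt[l] > 0L) {
        cnt[l] <- cnt[l] - 1L
        cur[pos] <<- l
        gen(pos + 1L, cnt)
        cnt[l] <- cnt[l] + 1L
      }
    }
  }
  gen(1L, counts)
  out
}

# p-value from the null draws; exhaustive nulls already contain the
# original labeling so no add-one correction is applied there. Values
# within a small relative tolerance of Delta_0 count as ties: relabelings
# equivalent to the original by symmetry (e.g. the two-cluster label
# swap) reproduce Delta_0 only up to floating-point round-off.
p_from_null <- function(delta0, null, mode, exhaustive) {
  eps <- 1e-8 * max(abs(delta0), abs(null))
  if (mode == "paper_literal_strict") {
    mean(null < delta0 - eps)
  } else if (exhaustive) {
    mean(null <= delta0 + eps)
  } else {
    (1 + sum(null <= delta0 + eps)) / (length(null) + 1)
  }
}

new_permutation_result <- function(delta_observed, delta_null, p_value,
                                   config, labels_compared, exhaustive,
                                   counts) {
  structure(
    list(delta_observed = delta_observed, delta_null = delta_null,
         p_value = p_value, n_permutations = length(delta_null),
         exhaustive = exhaustive, config = config,
         labels_compared = labels_compared, counts = counts),
    class = "mcs_permutation_result")
}

#' @export
print.mcs_permutation_result <- function(x, ...) {
  cat("Multidimensional cluster statistics permutation test\n")
  cat("  clusters compared:",
      if (identical(x$labels_compared, "global"))
        paste0("all ", length(x$counts), " (global)")
      else paste(x$labels_compared, collapse = " vs "), "\n")
  cat("  observed discrimination value Delta_0:",
      format(x$delta_observed), "\n")
  cat("  null:", x$n_permutations,
      if (x$exhaustive) "labelings (exhaustive enumeration)"
      else "random relabelings", "\n")
  cat("  p-value:", format(x$p_value),
      paste0("(", x$config$comparison_mode, ")"), "\n")
  invisible(x)
}

#' Permutation test for the disjointness of two clusters
#'
#' Tests whether the clusters labeled `a` and `b` are significantly
#' disjoint. Only points carrying one of the two labels participate. The
#' observed discrimination value `Delta_0` is compared against the null
#' distribution of discrimination values obtained by randomly relabeling
#' the points (class sizes preserved); small (negative) values of
#' `Delta_0` relative to the null indicate disjoint clusters. The
#' pairwise distances are computed once and reused across permutations —
#' only the assignment of labels to points changes.
#'
#' When the number of distinct labelings is small (at most
#' `n_permutations`, under `exhaustive = "auto"`) the null is enumerated
#' exhaustively and the p-value is exact.
#'
#' @param points an [mcs_pointset()].
#' @param a,b the two cluster labels to compare.
#' @param config a [permutation_config()].
#' @return an object of class `mcs_permutation_result` with elements
#'   `delta_observed`, `delta_null`, `p_value`, `n_permutations`,
#'   `exhaustive`, `config`, `labels_compared`, `counts`.
#' @examples
#' ps <- mcs_pointset(cbind(c(0, 1, 10, 11)), c("A", "A", "B", "B"))
#' permutation_test_pair(ps, "A", "B", permutation_config(seed = 1))
#' @export
permutation_test_pair <- function(points, a, b,
                                  config = permutation_config()) {
  stopifnot(inherits(points, "mcs_pointset"))
  a <- as.character(a); b <- as.character(b)
  if (identical(a, b)) stop("'a' and 'b' must be two distinct labels")
  sub <- subset_labels(points, c(a, b))
  check_testable(sub, c(a, b))
  D <- pairwise_distances(sub)
  m <- nrow(D)
  isA <- sub$labels == a
  nA <- sum(isA); nB <- m - nA
  r <- rowSums(D)
  S <- sum(D)
  # Delta for the two-cluster case from the within-A block sum alone:
  # SA = ordered within-A sum, cross = one-direction A-B sum,
  # SB follows from the fixed grand total S.
  delta_of <- function(idxA) {
    SA <- sum(D[idxA, idxA])
    cross <- sum(r[idxA]) - SA
    SB <- S - SA - 2 * cross
    SA / (nA * (nA - 1)) + SB / (nB * (nB - 1)) - 2 * cross / (nA * nB)
  }
  delta0 <- delta_of(which(isA))

  n_distinct <- choose(m, nA)
  exhaustive <- switch(config$exhaustive,
    auto = n_distinct <= config$n_permutations,
    never = FALSE,
    always = TRUE)

  if (exhaustive) {
    combos <- utils::combn(m, nA)
    null <- apply(combos, 2L, delta_of)
  } else {
    null <- with_config_seed(config$seed, {
      vapply(seq_len(config$n_permutations), function(i) {
        perm <- permute_indices(m, config$scheme, config$block_length)
        delta_of(which(isA[perm]))
      }, numeric(1))
    })
  }
  p <- p_from_null(delta0, null, config$comparison_mode, exhaustive)
  new_permutation_result(delta0, null, p, config, c(a, b), exhaustive,
                         stats::setNames(c(nA, nB), c(a, b)))
}

#' Global permutation test over all clusters
#'
#' Generalization of [permutation_test_pair()] to `L >= 2` clusters: the
#' statistic is the global discrimination value (the sum of the pairwise
#' discrimination values over all unordered label pairs, see
#' [global_discrimination()]) and permutations rearrange the full label
#' vector with all class sizes preserved.
#'
#' @inheritParams permutation_test_pair
#' @return an `mcs_permutation_result` with
#'   `labels_compared = "global"`.
#' @export
permutation_test_global <- function(points, config = permutation_config()) {
  stopifnot(inherits(points, "mcs_pointset"))
  check_testable(points)
  D <- pairwise_distances(points)
  m <- nrow(D)
  L <- length(points$label_order)
  f <- factor(points$labels, levels = points$label_order)
  li <- as.integer(f)
  n <- as.integer(table(f))
  delta_of <- function(li) {
    delta_global_from_blocks(block_mean_distances(D, li, L, n))
  }
  delta0 <- delta_of(li)

  n_distinct <- multiset_count(n)
  exhaustive <- switch(config$exhaustive,
    auto = n_distinct <= config$n_permutations,
    never = FALSE,
    always = TRUE)

  if (exhaustive) {
    arr <- multiset_permutations(n)
    null <- apply(arr, 1L, delta_of)
  } else {
    null <- with_config_seed(config$seed, {
      vapply(seq_len(config$n_permutations), function(i) {
        perm <- permute_indices(m, config$scheme, config$block_length)
        delta_of(li[perm])
      }, numeric(1))
    })
  }
  p <- p_from_null(delta0, null, config$comparison_mode, exhaustive)
  new_permutation_result(delta0, null, p, config, "global", exhaustive,
                         stats::setNames(n, points$label_order))
}

#' Matrix of pairwise cluster permutation p-values
#'
#' Runs [permutation_test_pair()] for every unordered pair of labels and
#' arranges the p-values in a symmetric `L x L` matrix (diagonal `NA`).
#' No multiplicity correction is applied by default; Holm-Bonferroni
#' adjustment of the off-diagonal p-values is available via `adjust`.
#' Each pair uses its own deterministic seed derived from `config$seed`
#' (when given), so results do not depend on the order in which pairs are
#' evaluated.
#'
#' @inheritParams permutation_test_pair
#' @param adjust `"none"` (default, raw mutual p-values) or `"holm"`.
#' @return a symmetric numeric matrix of p-values with label dimnames and
#'   attribute `"results"` holding the full per-pair
#'   `mcs_permutation_result` objects.
#' @export
pairwise_pvalue_matrix <- function(points, config = permutation_config(),
                                   adjust = c("none", "holm")) {
  stopifnot(inherits(points, "mcs_pointset"))
  adjust <- match.arg(adjust)
  check_testable(points)
  labs <- points$label_order
  L <- length(labs)
  pmat <- matrix(NA_real_, L, L, dimnames = list(labs, labs))
  results <- list()
  k <- 0L
  for (i in seq_len(L - 1L)) {
    for (j in seq((i + 1L), L)) {
      k <- k + 1L
      cfg <- config
      if (!is.null(config$seed)) cfg$seed <- as.integer(config$seed) + k
      res <- permutation_test_pair(points, labs[i], labs[j], cfg)
      pmat[i, j] <- pmat[j, i] <- res$p_value
      results[[paste(labs[i], labs[j], sep = ":")]] <- res
    }
  }
  if (adjust == "holm") {
    up <- upper.tri(pmat)
    pmat[up] <- stats::p.adjust(pmat[up], method = "holm")
    pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  }
  attr(pmat, "results") <- results
  attr(pmat, "adjust") <- adjust
  pmat
}
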