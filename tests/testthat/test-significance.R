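test_that("hypergeometric cell probabilities match binomial-coefficient arithmetic", {
  expect_equal(hypergeom_g(2, 2, 2, 2), 1 / 6)        # C(2,2)C(2,0)/C(4,2)
  expect_equal(hypergeom_g(2, 2, 2, 1), 4 / 6)        # C(2,1)C(2,1)/C(4,2)
  expect_equal(hypergeom_g(3, 3, 3, 4), 0)            # outside admissible range
  expect_equal(hypergeom_g(5, 3, 2, 0), 3 / 28)       # C(5,0)C(3,2)/C(8,2)
  expect_error(hypergeom_g(-1, 2, 1, 0), "nonnegative")
})

test_that("doubled-tail FET p-values match frozen enumerations and cap at 1", {
  # pmf {1/6, 4/6, 1/6}: tail set {0, 2}, doubled
  expect_equal(fet_pvalue(2, 2, 2, 2), 2 / 3)
  # pmf {1/20, 9/20, 9/20, 1/20}: tail set {0, 3}, doubled
  expect_equal(fet_pvalue(3, 3, 3, 3), 0.2)
  # single attainable table: doubled mass capped at 1
  expect_equal(fet_pvalue(2, 2, 4, 2), 1)
  res <- fet_pvalue(3, 3, 3, 3, details = TRUE)
  expect_equal(res$terms$a, 0:3)
  expect_equal(res$terms$included, c(TRUE, FALSE, FALSE, TRUE))
  expect_true(3 %in% res$terms$a[res$terms$included])  # observed always in
})

test_that("FET equals the exact-rational oracle on a grid of tables", {
  C <- pascal(30)
  for (n in c(6, 11, 17, 24, 30)) {
    for (np in seq(1, n - 1, by = 3)) {
      nn <- n - np
      for (d in 0:n) {
        for (a in max(0, d - nn):min(np, d)) {
          expect_equal(fet_pvalue(np, nn, d, a), oracle_fet(np, nn, d, a, C),
                       tolerance = 1e-12,
                       label = sprintf("table (%d,%d,%d,%d)", np, nn, d, a))
        }
      }
    }
  }
})

test_that("the R and compiled FET routes agree bitwise", {
  set.seed(4)
  pick <- function(v) v[sample.int(length(v), 1)]  # safe for length-1 ranges
  for (i in 1:200) {
    np <- pick(1:40)
    nn <- pick(1:40)
    d <- pick(0:(np + nn))
    a <- pick(max(0, d - nn):min(np, d))
    expect_identical(fet_pvalue(np, nn, d, a),
                     aspmine:::cpp_fet_pvalue(np, nn, d, a))
    expect_identical(hypergeom_g(np, nn, d, a),
                     aspmine:::cpp_hypergeom_g(np, nn, d, a))
    expect_identical(pvalue_lower_bound(np, nn, d),
                     aspmine:::cpp_pvalue_lower_bound(np, nn, d))
  }
})

test_that("the lower bound holds for a node and every descendant under any labeling", {
  expect_equal(pvalue_lower_bound(2, 2, 2), 1 / 6)
  expect_equal(pvalue_lower_bound(3, 3, 3), 1 / 20)
  d <- random_dataset(10, len_range = c(10, 16), seed = 21)
  np <- n_pos(d)
  nn <- n_neg(d)
  tab <- oracle_support_table(d)
  set.seed(22)
  for (rep in 1:3) {
    lab <- sample(d$label)
    # recompute d_pos under the permuted labels
    subs <- lapply(d$sequence, oracle_substrings)
    pat <- unlist(subs, use.names = FALSE)
    pl <- rep(lab, lengths(subs))
    dp <- table(factor(pat[pl == 1L], levels = tab$pattern))
    p_of <- stats::setNames(
      vapply(seq_len(nrow(tab)), function(i)
        fet_pvalue(np, nn, tab$d_all[i], as.integer(dp[i])), numeric(1)),
      tab$pattern)
    for (i in seq_len(nrow(tab))) {
      q <- tab$pattern[i]
      desc <- tab$pattern[startsWith(tab$pattern, q)]
      expect_true(all(pvalue_lower_bound(np, nn, tab$d_all[i]) <=
                        p_of[desc] + 1e-12),
                  label = sprintf("bound at %s, permutation %d", q, rep))
    }
  }
})

test_that("permutation plans preserve class sizes and are seed-reproducible", {
  d <- random_dataset(12, seed = 5)
  plan <- generate_permutations(d, 25, seed = 42)
  expect_equal(dim(plan$labels), c(12, 25))
  expect_true(all(colSums(plan$labels == 1L) == n_pos(d)))
  plan2 <- generate_permutations(d, 25, seed = 42)
  expect_identical(plan$labels, plan2$labels)
  plan3 <- generate_permutations(d, 25, seed = 43)
  expect_false(identical(plan$labels, plan3$labels))
  # uniformity: per-protein +1 frequency within 4-sigma binomial band
  d2 <- random_dataset(10, seed = 6)
  planM <- generate_permutations(d2, 4000, seed = 7)
  freq <- rowMeans(planM$labels == 1L)
  p0 <- n_pos(d2) / 10
  expect_true(all(abs(freq - p0) < 4 * sqrt(p0 * (1 - p0) / 4000)))
})

test_that("pruned calibration is bit-identical to the naive oracle", {
  for (seed in 1:4) {
    d <- random_dataset(18, len_range = c(15, 30), seed = seed)
    plan <- generate_permutations(d, 30, seed = seed + 50)
    fast <- wy_calibrate(d, plan, alpha = 0.1)
    naive <- wy_calibrate_naive(d, plan, alpha = 0.1)
    expect_identical(fast$min_p, naive$min_p)
    expect_identical(fast$delta, naive$delta)
    expect_identical(fast$fwer_estimate, naive$fwer_estimate)
    expect_gt(fast$stats$nodes_pruned, 0)
  }
  # min_support filtering agrees too
  d <- random_dataset(16, len_range = c(12, 20), seed = 11)
  plan <- generate_permutations(d, 20, seed = 61)
  expect_identical(wy_calibrate(d, plan, min_support = 3)$min_p,
                   wy_calibrate_naive(d, plan, min_support = 3)$min_p)
})

test_that("delta is the ceiling(alpha*M)-th smallest minimum and bounds the FWER estimate", {
  d <- random_dataset(14, seed = 8)
  plan <- generate_permutations(d, 20, seed = 9)
  cal <- wy_calibrate(d, plan, alpha = 0.05)
  expect_equal(cal$k, 1L)  # ceiling(0.05 * 20)
  expect_equal(cal$delta, sort(cal$min_p)[1])
  cal2 <- wy_calibrate(d, plan, alpha = 0.3)
  expect_equal(cal2$k, 6L)
  expect_equal(cal2$delta, sort(cal2$min_p)[6])
  expect_lte(cal2$fwer_estimate, (cal2$k - 1) / cal2$m_perms)
  expect_lt(cal2$fwer_estimate, 0.3)
})

test_that("adjusted p-values are empirical tail fractions of the minima", {
  plan <- structure(list(seed = 1L, m_perms = 6L), class = "permutation_plan")
  cal <- aspmine:::finalize_wy(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 0.34, plan)
  expect_equal(adjusted_pvalue(0.05, cal), 0)
  expect_equal(adjusted_pvalue(0.99, cal), 1)
  expect_equal(adjusted_pvalue(0.3, cal), 0.5)  # at the median of 6 minima
  expect_equal(adjusted_pvalue(c(0.15, 0.45), cal), c(1 / 6, 4 / 6))
  # monotone nondecreasing
  p <- sort(runif(20))
  expect_true(all(diff(adjusted_pvalue(p, cal)) >= 0))
})

test_that("Bonferroni reference level is alpha over the test count", {
  expect_equal(bonferroni_level(0.05, 100), 5e-4)
  expect_equal(signif(bonferroni_level(0.05, 3783825994), 2), 1.3e-11)
})
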