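#' Hypergeometric probability of a contingency-table cell
#'
#' Probability of finding a pattern in exactly `a` of the `n_pos` allergenic
#' proteins, conditional on the class sizes and the pattern's total support
#' `d_all`:
#' `choose(n_pos, a) * choose(n_neg, d_all - a) / choose(n_pos + n_neg, d_all)`.
#' Returns 0 outside the admissible range
#' `max(0, d_all - n_neg) <= a <= min(n_pos, d_all)`.
#'
#' Computed in log space via `lchoose()`; the compiled mining engine uses the
#' same libm calls in the same order so the two routes agree bitwise.
#'
#' @param n_pos,n_neg class sizes.
#' @param d_all pattern support (0..n).
#' @param a allergen-side support.
#' @return A probability.
#' @export
hypergeom_g <- function(n_pos, n_neg, d_all, a) {
  if (n_pos < 0 || n_neg < 0 || d_all < 0 || d_all > n_pos + n_neg)
    stop("counts must be nonnegative with d_all <= n_pos + n_neg")
  if (a < 0 || a > n_pos || d_all - a < 0 || d_all - a > n_neg) return(0)
  exp(lchoose(n_pos, a) + lchoose(n_neg, d_all - a) -
        lchoose(n_pos + n_neg, d_all))
}

#' Two-tailed Fisher exact test p-value for a pattern table
#'
#' Doubled-tail convention: the admissible counts whose point probability
#' does not exceed that of the observed table are summed and the sum is
#' doubled, then capped at 1. The observed table is always included.
#'
#' @inheritParams hypergeom_g
#' @param d_pos observed allergen-side support.
#' @param details if `TRUE`, also return the included tail terms.
#' @return The p-value, or (with `details = TRUE`) a list with `p_value` and
#'   a `terms` data.frame of `(a, g, included)`.
#' @examples
#' fet_pvalue(2, 2, 2, 2)  # 2/3
#' @export
fet_pvalue <- function(n_pos, n_neg, d_all, d_pos, details = FALSE) {
  if (d_pos < max(0, d_all - n_neg) || d_pos > min(n_pos, d_all))
    stop("d_pos outside the admissible range of the table")
  lo <- max(0L, d_all - n_neg)
  hi <- min(n_pos, d_all)
  gobs <- hypergeom_g(n_pos, n_neg, d_all, d_pos)
  cut <- gobs * (1 + 1e-7)  # tie tolerance, mirrored in the C++ engine
  s <- 0
  avals <- lo:hi
  gvals <- numeric(length(avals))
  inc <- logical(length(avals))
  for (i in seq_along(avals)) {
    ga <- hypergeom_g(n_pos, n_neg, d_all, avals[i])
    gvals[i] <- ga
    if (ga <= cut) {
      inc[i] <- TRUE
      s <- s + ga
    }
  }
  p <- 2 * s
  p <- if (p < 1) p else 1
  if (!details) return(p)
  list(p_value = p, terms = data.frame(a = avals, g = gvals, included = inc))
}

#' Lower bound on descendant p-values
#'
#' A label-free lower bound on the two-tailed FET p-value of a pattern with
#' support `d_all` and of all its rightward extensions: the smaller of the
#' two boundary-cell probabilities at the largest attainable support,
#' `min(g(min(d_all, n_pos), a = min(d_all, n_pos)), g(min(d_all, n_neg), a = 0))`.
#' Extensions can only lose support, and the boundary probabilities are
#' nonincreasing in support, so the bound holds along every branch; it is the
#' quantity that licenses branch-and-bound pruning of the pattern tree.
#'
#' @inheritParams hypergeom_g
#' @return A probability bounding every descendant's p-value from below.
#' @export
pvalue_lower_bound <- function(n_pos, n_neg, d_all) {
  stopifnot(d_all >= 0)
  min(hypergeom_g(n_pos, n_neg, min(d_all, n_pos), min(d_all, n_pos)),
      hypergeom_g(n_pos, n_neg, min(d_all, n_neg), 0))
}

#' Bonferroni reference level
#'
#' The per-test nominal level `alpha / n_tests`; provided as a reference
#' computation only (permutation calibration is the primary procedure).
#'
#' @param alpha target family-wise error rate.
#' @param n_tests number of simultaneous tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_level <- function(alpha, n_tests) alpha / n_tests

#' Generate a label-permutation plan
#'
#' Draws `m_perms` independent uniform permutations of the label vector
#' (labels shuffled globally across the whole dataset; categories and
#' sequences untouched), reproducibly from `seed`. Every permuted vector has
#' exactly `n_pos(dataset)` entries equal to +1.
#'
#' @param dataset a [protein_dataset()].
#' @param m_perms number of permutations M (>= 1).
#' @param seed RNG seed (required for reproducibility).
#' @return An object of class `permutation_plan`: list with `labels` (an
#'   `n x M` matrix of +1/-1), `m_perms`, `seed`.
#' @export
generate_permutations <- function(dataset, m_perms, seed) {
  stopifnot(m_perms >= 1)
  labs <- dataset$label
  set.seed(as.integer(seed))
  mat <- vapply(seq_len(m_perms), function(i) sample(labs),
                integer(length(labs)))
  structure(list(labels = mat, m_perms = as.integer(m_perms),
                 seed = as.integer(seed)),
            class = "permutation_plan")
}

finalize_wy <- function(min_p, alpha, plan, stats = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  m <- length(min_p)
  k <- as.integer(ceiling(alpha * m))
  delta <- sort(min_p)[k]
  structure(list(min_p = min_p, alpha = alpha, k = k, delta = delta,
                 fwer_estimate = mean(min_p < delta),
                 m_perms = m, seed = plan$seed, stats = stats),
            class = "wy_calibration")
}

#' Westfall-Young permutation calibration (pruned)
#'
#' For each permuted label vector, the minimum two-tailed FET p-value over
#' every pattern with support at least `min_support` is computed during a
#' single traversal of the pattern prefix tree. A subtree is cut when the
#' label-free lower bound of its p-values exceeds the largest running
#' minimum, so no permutation's minimum can be affected; the result is
#' exactly the full-enumeration vector (see [wy_calibrate_naive()], the
#' correctness oracle). The adjusted significance level `delta` is the k-th
#' smallest permutation minimum with `k = ceiling(alpha * M)`; a pattern is
#' declared significant when its raw p-value is strictly below `delta`,
#' which bounds the estimated family-wise error rate by `(k - 1)/M < alpha`.
#'
#' @param dataset a [protein_dataset()].
#' @param plan a [generate_permutations()] plan for this dataset.
#' @param alpha target FWER in (0, 1).
#' @param min_support minimum pattern support considered.
#' @return An object of class `wy_calibration`: `min_p` (length-M vector of
#'   per-permutation minima), `alpha`, `k`, `delta`, `fwer_estimate`,
#'   `m_perms`, `seed`, and traversal `stats` (`nodes_visited`,
#'   `nodes_pruned`).
#' @export
wy_calibrate <- function(dataset, plan, alpha = 0.05, min_support = 1L) {
  stopifnot(inherits(plan, "permutation_plan"),
            nrow(plan$labels) == nrow(dataset))
  res <- cpp_wy_minp(dataset$sequence, plan$labels == 1L,
                     n_pos(dataset), as.integer(min_support), TRUE)
  finalize_wy(res$min_p, alpha, plan,
              stats = list(nodes_visited = res$nodes_visited,
                           nodes_pruned = res$nodes_pruned))
}

#' Westfall-Young permutation calibration (naive oracle)
#'
#' Full enumeration without p-value pruning, implemented independently of
#' the compiled miner: all distinct substrings are collected into a sparse
#' pattern-by-protein presence matrix and per-permutation allergen-side
#' supports are obtained by matrix multiplication. Intended for small
#' datasets, as the correctness oracle for [wy_calibrate()].
#'
#' @inheritParams wy_calibrate
#' @return A `wy_calibration` (with `stats = NULL`).
#' @export
wy_calibrate_naive <- function(dataset, plan, alpha = 0.05, min_support = 1L) {
  stopifnot(inherits(plan, "permutation_plan"),
            nrow(plan$labels) == nrow(dataset))
  seqs <- dataset$sequence
  n <- length(seqs)
  np <- n_pos(dataset)
  nn <- n - np
  subs <- lapply(seqs, all_substrings)
  pat <- unlist(subs, use.names = FALSE)
  prot <- rep.int(seq_len(n), lengths(subs))
  f <- factor(pat)
  pres <- Matrix::sparseMatrix(i = as.integer(f), j = prot, x = 1,
                               dims = c(nlevels(f), n))
  d_all <- as.integer(Matrix::rowSums(pres))
  keep <- d_all >= min_support
  pres <- pres[keep, , drop = FALSE]
  d_all <- d_all[keep]
  m <- plan$m_perms
  if (!any(keep)) return(finalize_wy(rep(1, m), alpha, plan))
  dpos <- as.matrix(pres %*% ((plan$labels == 1L) * 1))
  # p-value lookup per unique (d_all, a)
  uds <- sort(unique(d_all))
  pv <- matrix(NA_real_, length(uds), np + 1L)
  for (r in seq_along(uds)) {
    d <- uds[r]
    for (a in max(0L, d - nn):min(np, d))
      pv[r, a + 1L] <- fet_pvalue(np, nn, d, a)
  }
  row <- match(d_all, uds)
  min_p <- vapply(seq_len(m), function(j) {
    min(pv[cbind(row, dpos[, j] + 1L)])
  }, numeric(1))
  finalize_wy(min_p, alpha, plan)
}

# all distinct substrings of one string (naive, for oracles and small data)
all_substrings <- function(s) {
  L <- nchar(s)
  st <- rep.int(seq_len(L), L:1)
  en <- st + sequence(L:1) - 1L
  unique(substring(s, st, en))
}

#' Empirical Westfall-Young adjusted p-value
#'
#' Fraction of permutation minima at or below the raw p-value,
#' `#\{m : min_p[m] <= p_raw\} / M`; monotone nondecreasing in `p_raw`.
#'
#' @param p_raw raw p-value(s).
#' @param calibration a `wy_calibration`.
#' @return Adjusted p-value(s) in `[0, 1]`.
#' @export
adjusted_pvalue <- function(p_raw, calibration) {
  stopifnot(inherits(calibration, "wy_calibration"))
  vapply(p_raw, function(p) mean(calibration$min_p <= p), numeric(1))
}

#' @export
print.wy_calibration <- function(x, ...) {
  cat(sprintf("Westfall-Young calibration: M = %d, alpha = %g\n",
              x$m_perms, x$alpha))
  cat(sprintf("  delta (k = %d-th smallest minimum) = %.6g\n", x$k, x$delta))
  cat(sprintf("  estimated FWER at delta = %.4f\n", x$fwer_estimate))
  if (!is.null(x$stats)) {
    cat(sprintf("  traversal: %g nodes visited, %g subtrees pruned\n",
                x$stats$nodes_visited, x$stats$nodes_pruned))
  }
  invisible(x)
}
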