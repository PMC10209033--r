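# Independent brute-force oracles and small fixture builders.  Everything
# here is deliberately naive and written without reference to the package
# internals it checks.

# random labeled dataset over a reduced alphabet
random_dataset <- function(n, len_range = c(20, 40),
                           alphabet = c("A", "C", "D", "E", "G", "H"),
                           n_cats = 3, seed = 1) {
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  lab <- sample(c(1L, -1L), n, replace = TRUE)
  if (all(lab == 1L)) lab[1] <- -1L
  if (all(lab == -1L)) lab[1] <- 1L
  protein_dataset(
    id = paste0("p", seq_len(n)),
    sequence = vapply(lens, function(L)
      paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1)),
    category = sample(paste0("c", seq_len(n_cats)), n, replace = TRUE),
    label = lab)
}

# all distinct substrings of one string, by explicit index grid
oracle_substrings <- function(s) {
  L <- nchar(s)
  idx <- expand.grid(i = seq_len(L), j = seq_len(L))
  idx <- idx[idx$j >= idx$i, ]
  unique(substring(s, idx$i, idx$j))
}

# hash-map support table: every distinct substring with its support triple
oracle_support_table <- function(dataset) {
  subs <- lapply(dataset$sequence, oracle_substrings)
  pat <- unlist(subs, use.names = FALSE)
  lab <- rep(dataset$label, lengths(subs))
  d_all <- table(pat)
  d_pos <- table(factor(pat[lab == 1L], levels = names(d_all)))
  data.frame(pattern = names(d_all),
             d_all = as.integer(d_all),
             d_pos = as.integer(d_pos),
             stringsAsFactors = FALSE)
}

# exact Pascal triangle; all entries are exact integers in doubles for n <= 40
pascal <- function(nmax) {
  C <- matrix(0, nmax + 1, nmax + 1)
  C[, 1] <- 1
  for (n in seq_len(nmax))
    for (k in seq_len(n))
      C[n + 1, k + 1] <- C[n, k] + C[n, k + 1]
  C
}

# exact-rational doubled-tail two-sided hypergeometric p-value: integer
# numerators compared exactly, single division at the end
oracle_fet <- function(n_pos, n_neg, d_all, d_pos, C = pascal(n_pos + n_neg)) {
  lo <- max(0, d_all - n_neg)
  hi <- min(n_pos, d_all)
  av <- lo:hi
  w <- C[n_pos + 1, av + 1] * C[n_neg + 1, d_all - av + 1]
  gobs <- w[d_pos - lo + 1]
  min(1, 2 * sum(w[w <= gobs]) / C[n_pos + n_neg + 1, d_all + 1])
}

# pairwise Mann-Whitney AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == -1]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# O(k^2) substring-containment maximality oracle
oracle_maximal <- function(strings) {
  strings <- unique(strings)
  keep <- vapply(seq_along(strings), function(i) {
    !any(vapply(seq_along(strings), function(j)
      j != i && nchar(strings[j]) > nchar(strings[i]) &&
        grepl(strings[i], strings[j], fixed = TRUE), logical(1)))
  }, logical(1))
  strings[keep]
}

# four-scenario category fixture: PSQQ (ASP via paired category), RRLE (ASP
# via two positive-only categories), MMKLE (single positive-only category),
# KLELS (leaks into a nonallergen).  Multiplicities are chosen so that every
# scenario pattern clears the doubled-tail FET at delta = 0.999 (n_pos = 10,
# n_neg = 3; e.g. the support-4 all-allergen table has p = 0.994).
scenario_dataset <- function() {
  protein_dataset(
    id = paste0("p", 1:13),
    sequence = c(rep("GGGPSQQGGGKLELS", 4),       # pairedA +
                 "GGGGGGGGGG",                    # pairedA -
                 "GGKLELSGG",                     # pairedA - (KLELS leak)
                 rep("GGRRLEGGMMKLEGGKLELS", 4),  # posonly1 +
                 "GGRRLEGGKLELS",                 # posonly2 +
                 "GGRRLEGGGKLELS",                # posonly2 +
                 "GGGGGGGG"),                     # negonly -
    category = c(rep("pairedA", 6), rep("posonly1", 4), rep("posonly2", 2),
                 "negonly"),
    label = c(1, 1, 1, 1, -1, -1, 1, 1, 1, 1, 1, 1, -1))
}
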