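#' Support of a single pattern
#'
#' Support is document frequency: the number of proteins containing the
#' pattern as a contiguous substring, each protein counted at most once
#' regardless of how many times the pattern occurs in it.
#'
#' @param dataset a [protein_dataset()].
#' @param pattern nonempty amino-acid string.
#' @return A list with `d_all`, `d_pos`, `d_neg`.
#' @examples
#' d <- protein_dataset(c("a", "b"), c("MKRREL", "KRRE"), c("x", "x"), c(1, -1))
#' count_support(d, "KRR")
#' @export
count_support <- function(dataset, pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) >= 1L)
  hit <- grepl(pattern, dataset$sequence, fixed = TRUE)
  list(d_all = sum(hit),
       d_pos = sum(hit & dataset$label == 1L),
       d_neg = sum(hit & dataset$label == -1L))
}

#' Enumerate contiguous patterns by prefix-tree traversal
#'
#' Walks the prefix tree of all contiguous patterns occurring in the dataset
#' in depth-first order, children ordered alphabetically, growing each node's
#' occurrence list from its parent's (projected-database extension). Every
#' pattern with support at least `min_support` and length at most
#' `max_length` is visited exactly once, except inside subtrees cut by
#' `prune`. Support anti-monotonicity guarantees that support-based pruning
#' misses nothing above threshold.
#'
#' @param dataset a [protein_dataset()].
#' @param min_support minimum document frequency (>= 1).
#' @param max_length optional cap on pattern length (default unlimited).
#' @param visit optional callback `function(pattern, d_all, d_pos, d_neg)`
#'   invoked at every visited node.
#' @param prune optional predicate with the same signature; returning `TRUE`
#'   stops extension of the current pattern (its subtree is skipped).
#' @param collect if `TRUE` (default) return the visited patterns and their
#'   support triples.
#' @return A list with `patterns` (a `data.frame`: `pattern`, `d_all`,
#'   `d_pos`, `d_neg`; `NULL` when `collect = FALSE`), `nodes_visited`, and
#'   `nodes_pruned`.
#' @examples
#' d <- protein_dataset("p", "MKRRELEK", "x", 1)
#' enumerate_patterns(d)$nodes_visited  # 33 distinct patterns
#' @export
enumerate_patterns <- function(dataset, min_support = 1L, max_length = Inf,
                               visit = NULL, prune = NULL, collect = TRUE) {
  stopifnot(min_support >= 1L)
  ml <- if (is.infinite(max_length)) -1L else as.integer(max_length)
  res <- cpp_enumerate(dataset$sequence, dataset$label,
                       as.integer(min_support), ml, collect, visit, prune)
  patterns <- NULL
  if (collect) {
    patterns <- data.frame(pattern = res$pattern, d_all = res$d_all,
                           d_pos = res$d_pos, d_neg = res$d_all - res$d_pos,
                           stringsAsFactors = FALSE)
  }
  list(patterns = patterns,
       nodes_visited = res$nodes_visited,
       nodes_pruned = res$nodes_pruned)
}

#' Count distinct contiguous patterns
#'
#' Number of distinct substrings across all sequences, computed with a
#' generalized suffix automaton (linear in total sequence length, hence
#' subquadratic; the naive hash-set enumeration serves as test oracle).
#'
#' @param x a [protein_dataset()] or a character vector of sequences.
#' @return A numeric count (may exceed the integer range on large inputs).
#' @examples
#' count_distinct_patterns("MKRRELEK")  # 33
#' @export
count_distinct_patterns <- function(x) {
  seqs <- if (inherits(x, "protein_dataset")) x$sequence else toupper(as.character(x))
  cpp_count_distinct(seqs)
}

#' Number of possible patterns up to a length
#'
#' Exact value of `sum(alphabet_size^k, k = 1..max_len)` in arbitrary
#' precision (the count overflows doubles already for a 20-letter alphabet
#' at length 50, where it exceeds 10^65).
#'
#' @param alphabet_size number of residues (>= 1).
#' @param max_len maximum pattern length (>= 1).
#' @return The exact count as a decimal string.
#' @examples
#' possible_pattern_count(20, 2)  # "420"
#' @export
possible_pattern_count <- function(alphabet_size, max_len) {
  stopifnot(alphabet_size >= 1, max_len >= 1)
  a <- as.numeric(alphabet_size)
  acc <- big_zero()
  pw <- big_one()
  for (k in seq_len(max_len)) {
    pw <- big_mul_small(pw, a)
    acc <- big_add(acc, pw)
  }
  big_to_string(acc)
}

#' @rdname possible_pattern_count
#' @param x a nonnegative decimal integer string.
#' @return `decimal_log10()`: the base-10 logarithm of `x` as a double.
#' @export
decimal_log10 <- function(x) {
  x <- sub("^0+(?=.)", "", x, perl = TRUE)
  lead <- as.numeric(substr(x, 1L, min(15L, nchar(x))))
  (nchar(x) - min(15L, nchar(x))) + log10(lead)
}

# --- minimal arbitrary-precision nonnegative integers -----------------------
# little-endian limbs in base 1e7, stored as doubles; products limb * m stay
# below 2^53 for multipliers up to ~9e8, ample for residue alphabets

BIG_BASE <- 1e7

big_zero <- function() 0
big_one <- function() 1

big_mul_small <- function(x, m) {
  carry <- 0
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    v <- x[i] * m + carry
    out[i] <- v %% BIG_BASE
    carry <- (v - out[i]) / BIG_BASE
  }
  while (carry > 0) {
    out <- c(out, carry %% BIG_BASE)
    carry <- (carry - carry %% BIG_BASE) / BIG_BASE
  }
  out
}

big_add <- function(x, y) {
  n <- max(length(x), length(y))
  x <- c(x, numeric(n - length(x)))
  y <- c(y, numeric(n - length(y)))
  out <- numeric(n)
  carry <- 0
  for (i in seq_len(n)) {
    v <- x[i] + y[i] + carry
    out[i] <- v %% BIG_BASE
    carry <- (v - out[i]) / BIG_BASE
  }
  if (carry > 0) out <- c(out, carry)
  out
}

big_to_string <- function(x) {
  digs <- vapply(rev(x), function(d) sprintf("%07.0f", d), character(1))
  s <- sub("^0+(?=.)", "", paste(digs, collapse = ""), perl = TRUE)
  s
}
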