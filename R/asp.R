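#' Mine significant patterns at a fixed nominal level
#'
#' Traverses the pattern prefix tree collecting every pattern whose
#' two-tailed FET p-value is strictly below `delta` and whose empirical
#' frequency is higher on the requested side
#' (`d_pos/n_pos > d_neg/n_neg` for the allergen side, reversed otherwise;
#' the two-tailed p-value itself carries no direction). Subtrees whose
#' p-value lower bound exceeds `delta` are cut.
#'
#' @param dataset a [protein_dataset()].
#' @param delta nominal significance level in (0, 1), typically the
#'   `delta` of a [wy_calibrate()] result.
#' @param direction `"allergen"` or `"nonallergen"` enrichment side.
#' @param min_support minimum pattern support.
#' @return A `data.frame` with columns `pattern`, `d_all`, `d_pos`, `d_neg`,
#'   `p_raw`, and a list-column `presence` of 1-based indices of the
#'   proteins containing each pattern; traversal statistics are attached as
#'   attribute `"stats"`.
#' @export
find_significant_patterns <- function(dataset, delta,
                                      direction = c("allergen", "nonallergen"),
                                      min_support = 1L) {
  stopifnot(delta > 0, delta < 1)
  direction <- match.arg(direction)
  res <- cpp_significant(dataset$sequence, dataset$label, delta,
                         if (direction == "allergen") 1L else -1L,
                         as.integer(min_support))
  out <- data.frame(pattern = as.character(res$pattern),
                    d_all = as.integer(res$d_all),
                    d_pos = as.integer(res$d_pos),
                    d_neg = as.integer(res$d_all) - as.integer(res$d_pos),
                    p_raw = as.numeric(res$p_raw),
                    stringsAsFactors = FALSE)
  out$presence <- if (nrow(out)) res$presence else list()
  attr(out, "stats") <- list(nodes_visited = res$nodes_visited,
                             nodes_pruned = res$nodes_pruned)
  out
}

asp_annotate <- function(candidates, dataset, profile, calibration) {
  paired <- profile$category[profile$type == "paired"]
  posonly <- profile$category[profile$type == "positive_only"]
  cats <- lapply(candidates$presence,
                 function(idx) unique(dataset$category[idx]))
  candidates$categories <- cats
  candidates$n_categories <- lengths(cats)
  candidates$cond2 <- candidates$d_neg == 0L
  candidates$cond3a <- vapply(cats, function(g) any(g %in% paired), logical(1))
  candidates$cond3b <- vapply(cats, function(g) sum(g %in% posonly) >= 2L,
                              logical(1))
  candidates$p_adj <- if (!is.null(calibration))
    adjusted_pvalue(candidates$p_raw, calibration) else NA_real_
  candidates
}

#' Select allergen-specific patterns (ASPs)
#'
#' Applies the ASP screen to allergen-enriched significant patterns. An ASP
#' must (2) be absent from every nonallergenic protein and (3) not be
#' attributable to a single biological category, established by occurring in
#' at least one paired category (3a) or in at least two distinct
#' positive-only categories (3b). Condition (1), statistical significance,
#' is inherited from the candidate set.
#'
#' @param candidates output of [find_significant_patterns()] mined on the
#'   allergen side.
#' @param dataset the [protein_dataset()] the candidates were mined from.
#' @param profile its [classify_categories()] profile (recomputed if
#'   omitted).
#' @param calibration optional [wy_calibrate()] result used to attach
#'   empirical adjusted p-values.
#' @param keep_all if `TRUE`, return every candidate with its condition
#'   flags instead of only the accepted ASPs.
#' @return A `data.frame` of ASP records with columns of the candidate set
#'   plus `categories` (list), `n_categories`, `cond2`, `cond3a`, `cond3b`,
#'   `p_adj`, and `direction = "allergen_enriched"`.
#' @export
select_asps <- function(candidates, dataset, profile = classify_categories(dataset),
                        calibration = NULL, keep_all = FALSE) {
  ann <- asp_annotate(candidates, dataset, profile, calibration)
  ann$direction <- rep("allergen_enriched", nrow(ann))
  ann$is_asp <- ann$cond2 & (ann$cond3a | ann$cond3b)
  if (keep_all) return(ann)
  out <- ann[ann$is_asp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select non-ASPs (nonallergen-enriched predictive patterns)
#'
#' Non-ASPs feed the predictor only: they must be significantly more
#' frequent in nonallergenic proteins but may still occur in a few
#' allergens, so the absence condition of ASPs does not apply. The
#' category-specificity screen mirrors the ASP one: a non-ASP must occur in
#' at least one paired category, or in at least two distinct categories
#' overall (with a single negative-only category, a pattern confined to it
#' cannot be told apart from a category-specific one).
#'
#' @inheritParams select_asps
#' @param candidates output of [find_significant_patterns()] mined on the
#'   nonallergen side.
#' @return A `data.frame` of records with `direction =
#'   "nonallergen_enriched"`.
#' @export
select_non_asps <- function(candidates, dataset,
                            profile = classify_categories(dataset),
                            calibration = NULL, keep_all = FALSE) {
  ann <- asp_annotate(candidates, dataset, profile, calibration)
  ann$direction <- rep("nonallergen_enriched", nrow(ann))
  ann$is_asp <- ann$cond3a | ann$n_categories >= 2L
  if (keep_all) return(ann)
  out <- ann[ann$is_asp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary distributions of a set of ASP records
#'
#' The five descriptive distributions reported for mined pattern sets:
#' pattern lengths, adjusted p-values, supports, patterns per allergenic
#' protein, and categories per pattern.
#'
#' @param records a `data.frame` from [select_asps()]/[select_non_asps()].
#' @param dataset optionally, the source [protein_dataset()]; required for
#'   the patterns-per-protein distribution.
#' @return A list of histogram tables (empty tables for empty input).
#' @export
asp_report <- function(records, dataset = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    empty <- table(integer(0))
    return(list(length_hist = empty, p_adj_hist = empty,
                support_hist = empty, asps_per_protein = empty,
                categories_per_asp = empty))
  }
  per_protein <- table(integer(0))
  if (!is.null(dataset)) {
    counts <- integer(nrow(dataset))
    for (idx in records$presence) counts[idx] <- counts[idx] + 1L
    per_protein <- table(counts[dataset$label == 1L])
  }
  list(length_hist = table(nchar(records$pattern)),
       p_adj_hist = table(signif(records$p_adj, 3)),
       support_hist = table(records$d_all),
       asps_per_protein = per_protein,
       categories_per_asp = table(records$n_categories))
}

#' Write an ASP table as TSV
#'
#' @param records ASP records.
#' @param path output path.
#' @param header optional comment lines (each prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_asp_table <- function(records, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(pattern = records$pattern,
                   length = nchar(records$pattern),
                   d_all = records$d_all, d_pos = records$d_pos,
                   d_neg = records$d_neg, p_raw = records$p_raw,
                   p_adj = records$p_adj, cond2 = records$cond2,
                   cond3a = records$cond3a, cond3b = records$cond3b,
                   n_categories = records$n_categories,
                   categories = vapply(records$categories, paste,
                                       character(1), collapse = ";"),
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
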