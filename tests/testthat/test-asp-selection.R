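test_that("significant-pattern mining matches a brute-force FET screen", {
  cfg <- planted_config(31, n_motifs = 1, p_pos = 0.8)
  d <- generate_dataset(cfg)$dataset
  delta <- 1e-6
  sig <- find_significant_patterns(d, delta, "allergen")
  # independent check: mine everything, test every pattern directly
  tab <- enumerate_patterns(d)$patterns
  np <- n_pos(d)
  nn <- n_neg(d)
  keep <- vapply(seq_len(nrow(tab)), function(i) {
    tab$d_pos[i] / np > tab$d_neg[i] / nn &&
      fet_pvalue(np, nn, tab$d_all[i], tab$d_pos[i]) < delta
  }, logical(1))
  expect_setequal(sig$pattern, tab$pattern[keep])
  expect_true(all(sig$p_raw < delta))
  # presence lists are faithful
  for (i in seq_len(min(5, nrow(sig)))) {
    expect_equal(sort(sig$presence[[i]]),
                 which(grepl(sig$pattern[i], d$sequence, fixed = TRUE)))
  }
  # a delta below the smallest attainable p returns nothing
  expect_equal(nrow(find_significant_patterns(d, 1e-60, "allergen")), 0)
})

test_that("mirroring the labels mirrors the enrichment sides", {
  d <- random_dataset(20, len_range = c(15, 25), seed = 13)
  m <- d
  m$label <- -m$label
  a <- find_significant_patterns(d, 0.2, "allergen")
  b <- find_significant_patterns(m, 0.2, "nonallergen")
  expect_setequal(a$pattern, b$pattern)
  ord_a <- order(a$pattern)
  ord_b <- order(b$pattern)
  expect_equal(a$d_pos[ord_a], b$d_neg[ord_b])
  expect_equal(a$p_raw[ord_a], b$p_raw[ord_b])
})

test_that("the four category scenarios decide ASP status as designed", {
  d <- scenario_dataset()
  prof <- classify_categories(d)
  cand <- find_significant_patterns(d, 0.999, "allergen")
  ann <- select_asps(cand, d, prof, keep_all = TRUE)
  row_of <- function(p) ann[ann$pattern == p, ]

  # leaks into a nonallergen: fails the absence condition
  expect_true("KLELS" %in% ann$pattern)
  expect_false(row_of("KLELS")$cond2)
  expect_false(row_of("KLELS")$is_asp)

  # confined to allergens of a paired category: accepted via 3a
  expect_true(row_of("PSQQ")$cond2)
  expect_true(row_of("PSQQ")$cond3a)
  expect_true(row_of("PSQQ")$is_asp)

  # shared by two positive-only categories: accepted via 3b
  expect_true(row_of("RRLE")$cond2)
  expect_false(row_of("RRLE")$cond3a)
  expect_true(row_of("RRLE")$cond3b)
  expect_true(row_of("RRLE")$is_asp)

  # single positive-only category: category-specific, rejected
  expect_true(row_of("MMKLE")$cond2)
  expect_false(row_of("MMKLE")$cond3a)
  expect_false(row_of("MMKLE")$cond3b)
  expect_false(row_of("MMKLE")$is_asp)

  asps <- select_asps(cand, d, prof)
  expect_true(all(c("PSQQ", "RRLE") %in% asps$pattern))
  expect_false(any(c("KLELS", "MMKLE") %in% asps$pattern))
})

test_that("emitted ASPs survive an independent re-check of all three conditions", {
  cfg <- planted_config(17, n_motifs = 2, p_pos = 0.9)
  gen <- generate_dataset(cfg)
  d <- gen$dataset
  plan <- generate_permutations(d, 100, seed = 3)
  cal <- wy_calibrate(d, plan)
  cand <- find_significant_patterns(d, cal$delta, "allergen")
  asps <- select_asps(cand, d, calibration = cal)
  expect_gt(nrow(asps), 0)
  prof <- classify_categories(d)
  paired <- prof$category[prof$type == "paired"]
  posonly <- prof$category[prof$type == "positive_only"]
  for (i in seq_len(nrow(asps))) {
    hit <- grepl(asps$pattern[i], d$sequence, fixed = TRUE)
    expect_equal(sum(hit & d$label == -1L), 0)                    # condition 2
    cats <- unique(d$category[hit])
    expect_true(any(cats %in% paired) || sum(cats %in% posonly) >= 2)  # 3
    expect_lt(fet_pvalue(n_pos(d), n_neg(d), sum(hit),
                         sum(hit & d$label == 1L)), cal$delta)    # condition 1
  }
  # planted motifs recovered (as themselves or a sub/superstring)
  for (m in cfg$motifs$motif) {
    expect_true(any(vapply(asps$pattern, function(p)
      grepl(p, m, fixed = TRUE) || grepl(m, p, fixed = TRUE), logical(1))),
      label = sprintf("motif %s recovered", m))
  }
  expect_true(all(adjusted_pvalue(asps$p_raw, cal) == asps$p_adj))
})

test_that("non-ASP screening keeps multi-category nonallergen-enriched patterns", {
  # QWERT enriched in nonallergens across a paired and the negative-only
  # category; VVVVV confined to the single negative-only category
  d <- protein_dataset(
    id = paste0("p", 1:10),
    sequence = c("GGGGGGG", "GGGGGGG", "GGQWERTGG", "GGQWERTGG",
                 "GGGGGGG", "GGGGGGG",
                 "QWERTGGVVVVV", "GGQWERTGGVVVVV", "GGVVVVVQWERT", "VVVVVGGQWERT"),
    category = c(rep("pairedA", 4), rep("posonly1", 2), rep("negonly", 4)),
    label = c(1, 1, -1, -1, 1, 1, -1, -1, -1, -1))
  cand <- find_significant_patterns(d, 0.999, "nonallergen")
  sel <- select_non_asps(cand, d, keep_all = TRUE)
  expect_true(sel[sel$pattern == "QWERT", "is_asp"])
  expect_false(sel[sel$pattern == "VVVVV", "is_asp"])
  # allergen-leaning patterns are never candidates on this side
  expect_false("GGG" %in% cand$pattern ||
                 any(cand$d_pos / n_pos(d) >= cand$d_neg / n_neg(d)))
})

test_that("report histograms summarize lengths, supports and category spread", {
  rec <- data.frame(pattern = c("MKRR", "ELKARRA"), d_all = c(3L, 2L),
                    d_pos = c(3L, 2L), d_neg = c(0L, 0L),
                    p_raw = c(1e-4, 1e-3), p_adj = c(0, 0.01),
                    n_categories = c(2L, 1L))
  rec$presence <- list(c(1L, 2L, 3L), c(1L, 4L))
  rep1 <- asp_report(rec)
  expect_equal(as.integer(rep1$length_hist[c("4", "7")]), c(1L, 1L))
  expect_equal(as.integer(rep1$support_hist[c("2", "3")]), c(1L, 1L))
  expect_equal(as.integer(rep1$categories_per_asp[c("1", "2")]), c(1L, 1L))
  d <- protein_dataset(paste0("p", 1:4), rep("MK", 4), rep("c", 4),
                       c(1, 1, 1, 1))
  rep2 <- asp_report(rec, d)
  # protein 1 carries both patterns, proteins 2-4 carry one each
  expect_equal(as.integer(rep2$asps_per_protein[c("1", "2")]), c(3L, 1L))
  # degenerate input: empty tables, no crash
  rep0 <- asp_report(rec[0, ])
  expect_equal(length(rep0$length_hist), 0)
})
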