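test_that("indicator and k-mer-ratio feature matrices are as defined", {
  spec <- feature_spec(c("MK", "RR"), "binary_indicator")
  X <- build_feature_matrix(c("MKRREL", "ELELEL"), spec)
  expect_equal(unname(X), rbind(c(1, 1), c(0, 0)))
  expect_equal(X[1, ], c(MK = 1, RR = 1))
  expect_equal(unname(build_feature_matrix("MKRREL",
                                           feature_spec("WWW", "binary_indicator"))),
               matrix(0, 1, 1))
  spec1 <- feature_spec(c("A", "B"), "kmer_ratio", k = 1)
  expect_equal(build_feature_matrix("AAB", spec1)[1, ],
               c(A = 2 / 3, B = 1 / 3))
  spec2 <- feature_spec(c("AB", "BA"), "kmer_ratio", k = 2)
  expect_equal(build_feature_matrix("ABAB", spec2)[1, ],
               c(AB = 2 / 3, BA = 1 / 3))
  expect_warning(X3 <- build_feature_matrix("A", spec2), "shorter")
  expect_equal(unname(X3[1, ]), c(0, 0))
  expect_error(feature_spec("AA", "kmer_ratio"), "requires k")
  expect_error(feature_spec(c("A", "A"), "binary_indicator"), "unique")
})

test_that("k-mer specs honor kind and support thresholds", {
  d <- random_dataset(10, seed = 2, alphabet = c("A", "C", "D"))
  s1 <- kmer_feature_spec(d, 1)
  expect_equal(s1$kind, "kmer_ratio")
  expect_lte(length(s1$patterns), 26)
  d6 <- protein_dataset(paste0("p", 1:3),
                        c("AAACCCGGG", "TTAAACCCG", "AAACCCTTT"),
                        rep("x", 3), c(1, 1, -1))
  s6 <- kmer_feature_spec(d6, 6, support_threshold = 2)
  expect_true("AAACCC" %in% s6$patterns)
  expect_equal(s6$kind, "binary_indicator")
  # every selected 6-mer really reaches the threshold
  for (p in s6$patterns)
    expect_gte(sum(grepl(p, d6$sequence, fixed = TRUE)), 2)
  expect_warning(s0 <- kmer_feature_spec(d6, 6, support_threshold = 100),
                 "empty")
  expect_equal(length(s0$patterns), 0)
})

test_that("the linear SVM minimizes the soft-margin objective", {
  # separable 2-point problem at large C: correct at threshold zero
  X <- rbind(c(1, 0), c(0, 1))
  m <- train_linear_svm(X, c(1, -1), C = 100)
  expect_true(svm_decision(m, X)[1] > 0 && svm_decision(m, X)[2] < 0)
  # C -> 0 shrinks the weights toward zero
  set.seed(10)
  Xr <- matrix(rnorm(60), 20, 3)
  yr <- ifelse(Xr[, 1] + 0.5 * Xr[, 2] > 0, 1, -1)
  w_small <- train_linear_svm(Xr, yr, C = 1e-4)$weights
  w_big <- train_linear_svm(Xr, yr, C = 1)$weights
  expect_lt(sqrt(sum(w_small^2)), 0.05)
  expect_lt(sqrt(sum(w_small^2)), sqrt(sum(w_big^2)))
  expect_error(train_linear_svm(Xr, rep(1, 20), C = 1), "both classes")
})

test_that("the SVM objective matches an independent convex QP oracle", {
  skip_if_not_installed("kernlab")
  set.seed(12)
  n <- 20
  X <- matrix(rnorm(2 * n), n, 2)
  y <- ifelse(X[, 1] + X[, 2] + 0.3 * rnorm(n) > 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  C <- 1
  m <- train_linear_svm(X, y, C)
  obj_impl <- aspmine:::svm_objective(m$weights, m$intercept, X, y, C)
  # oracle: box-constrained dual QP via interior-point solver
  Q <- (y %o% y) * (X %*% t(X))
  sol <- kernlab::ipop(c = matrix(-1, n), H = Q, A = matrix(y, 1),
                       b = 0, l = matrix(0, n), u = matrix(C, n), r = 0,
                       sigf = 9)
  alpha <- kernlab::primal(sol)
  w <- drop(t(X) %*% (alpha * y))
  on_margin <- alpha > 1e-5 * C & alpha < (1 - 1e-5) * C
  b <- mean(y[on_margin] - X[on_margin, , drop = FALSE] %*% w)
  obj_oracle <- aspmine:::svm_objective(w, b, X, y, C)
  expect_equal(obj_impl, obj_oracle, tolerance = 1e-4)
})

test_that("metrics match hand computations and the Mann-Whitney oracle", {
  # perfect separation
  mper <- compute_metrics(c(2, 1, -1, -2), c(1, 1, -1, -1))
  expect_equal(mper$auc, 1)
  expect_equal(mper$auc10, 1)
  expect_equal(mper$f1, 1)
  expect_equal(mper$mcc, 1)
  # TP=2 FP=1 TN=1 FN=0
  m2 <- compute_metrics(c(1, 1, 1, -1), c(1, 1, -1, -1))
  expect_equal(unname(m2$confusion), c(2, 1, 1, 0))
  expect_equal(m2$f1, 0.8)
  expect_equal(m2$mcc, (2 * 1 - 1 * 0) / sqrt(3 * 2 * 2 * 1))
  # rank AUC equals the pairwise-comparison statistic exactly
  set.seed(14)
  for (i in 1:5) {
    sc <- round(rnorm(60), 1)  # rounding forces ties
    lb <- sample(c(1, -1), 60, replace = TRUE)
    if (length(unique(lb)) < 2) lb[1] <- -lb[1]
    expect_equal(compute_metrics(sc, lb)$auc, oracle_auc(sc, lb),
                 tolerance = 1e-12)
  }
  # constant classifier: diagonal ROC, AUC-10% at the chance level 0.05
  mc <- compute_metrics(rep(0.5, 40), rep(c(1, -1), 20))
  expect_equal(mc$auc, 0.5)
  expect_equal(mc$auc10, 10 * 0.5 * 0.1^2)
  # uninformative scores at large n: AUC near one half
  set.seed(15)
  scb <- rnorm(10000)
  lbb <- sample(c(1, -1), 10000, replace = TRUE)
  expect_lt(abs(compute_metrics(scb, lbb)$auc - 0.5), 0.02)
  # MCC centers on zero under label permutation
  set.seed(16)
  mccs <- replicate(200, compute_metrics(scb[1:200], sample(lbb[1:200]))$mcc)
  expect_lt(abs(mean(mccs)), 0.05)
  expect_true(all(mccs >= -1 & mccs <= 1))
  # single-class labels: AUC undefined with warning
  expect_warning(mna <- compute_metrics(c(1, 2), c(1, 1)), "single-class")
  expect_true(is.na(mna$auc))
})

test_that("C selection extends once and ties resolve to the smallest C", {
  # features perfectly separate within every inner fold: score constant in C
  d <- protein_dataset(
    paste0("p", 1:12),
    rep(c("AAAWWWAAA", "AAAAAAAAA"), 6),
    rep(c("c1", "c1", "c2", "c2", "c3", "c3"), 2),
    rep(c(1, -1), 6))
  spec <- feature_spec("WWW", "binary_indicator")
  res <- select_C(d, spec, metric = "auc")
  expect_equal(nrow(res$grid), 11)            # 10-value grid + one extension
  expect_equal(res$log10_C, min(res$grid$log10_C))
  expect_equal(res$log10_C, -27 / 9 - 4 / 9)  # smallest C of the extended grid
  expect_true(all(res$grid$score == 1))
})

test_that("leave-category-out folds are disjoint, exhaustive and leakage-free", {
  # paired_1 enlarged so that a pattern exclusive to it can clear delta
  cats <- default_categories()
  cats$n_pos[cats$name == "paired_1"] <- 30L
  cfg <- planted_config(3, n_motifs = 2, p_pos = 0.85, categories = cats)
  d <- generate_dataset(cfg)$dataset
  cv <- leave_category_out_cv(d, "kmer1", seed = 2, C = 1)
  prof <- classify_categories(d)
  paired <- prof$category[prof$type == "paired"]
  expect_equal(sort(unique(cv$predictions$category)), sort(paired))
  expect_equal(nrow(cv$predictions),
               sum(d$category %in% paired))
  expect_false(anyDuplicated(cv$predictions$id) > 0)

  # leakage: a motif unique to one held-out category must not be mined into
  # that fold's features
  uniq <- "WWWWHHHH"
  d2 <- d
  sel <- which(d2$category == paired[1] & d2$label == 1L)
  for (i in sel) {
    s <- d2$sequence[i]
    d2$sequence[i] <- paste0(uniq, substr(s, nchar(uniq) + 1, nchar(s)))
  }
  cv2 <- leave_category_out_cv(d2, "asp", m_perms = 60, seed = 2, C = 1)
  in_fold <- any(vapply(cv2$fold_features[[paired[1]]], function(p)
    grepl(p, uniq, fixed = TRUE) || grepl(uniq, p, fixed = TRUE), logical(1)))
  expect_false(in_fold)
  # while mining WITH that category present does find it
  mf_full <- mine_features(d2, m_perms = 60, seed = 2)
  expect_true(any(vapply(mf_full$asps$pattern, function(p)
    grepl(p, uniq, fixed = TRUE) || grepl(uniq, p, fixed = TRUE), logical(1))))
})
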