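#' Feature specifications for sequence classification
#'
#' A feature spec names an ordered set of feature-defining patterns and how
#' they map to numbers: `binary_indicator` sets `x[i, j] = 1` when pattern j
#' is a substring of sequence i; `kmer_ratio` sets `x[i, j]` to the fraction
#' of the `length - k + 1` k-mers of sequence i equal to k-mer j.
#'
#' @param patterns character vector of unique feature-defining patterns.
#' @param kind `"binary_indicator"` or `"kmer_ratio"`.
#' @param k k-mer length; required for `kmer_ratio`.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(patterns, kind = c("binary_indicator", "kmer_ratio"),
                         k = NULL) {
  kind <- match.arg(kind)
  patterns <- as.character(patterns)
  if (anyDuplicated(patterns)) stop("feature patterns must be unique")
  if (kind == "kmer_ratio" && is.null(k)) stop("kmer_ratio requires k")
  structure(list(patterns = patterns, kind = kind,
                 k = if (is.null(k)) NA_integer_ else as.integer(k)),
            class = "feature_spec")
}

#' k-mer feature specification from a training set
#'
#' For `k = 6` (and other large k), binary indicators over the k-mers whose
#' document frequency is at least `support_threshold` (default 15). For
#' `k` of 1 or 2, ratio features over all observed k-mers with no threshold.
#'
#' @param dataset a [protein_dataset()] (training portion only).
#' @param k k-mer length.
#' @param support_threshold minimum document frequency for indicator k-mers.
#' @return A [feature_spec()].
#' @export
kmer_feature_spec <- function(dataset, k, support_threshold = 15L) {
  stopifnot(k >= 1)
  if (k <= 2) {
    kmers <- sort(unique(unlist(lapply(dataset$sequence, seq_kmers, k = k),
                                use.names = FALSE)))
    return(feature_spec(kmers, "kmer_ratio", k = k))
  }
  per_prot <- lapply(dataset$sequence, function(s) unique(seq_kmers(s, k)))
  df <- table(unlist(per_prot, use.names = FALSE))
  kmers <- sort(names(df)[df >= support_threshold])
  if (length(kmers) == 0L)
    warning("no ", k, "-mer reaches support ", support_threshold,
            "; empty feature spec")
  feature_spec(kmers, "binary_indicator", k = k)
}

seq_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

#' Build a feature matrix
#'
#' @param dataset a [protein_dataset()] or character vector of sequences.
#' @param spec a [feature_spec()].
#' @return A numeric matrix (proteins x features) with the patterns as
#'   column names; entries lie in `[0, 1]`. Sequences shorter than `k`
#'   under `kmer_ratio` get an all-zero row with a warning.
#' @export
build_feature_matrix <- function(dataset, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  seqs <- if (inherits(dataset, "protein_dataset")) dataset$sequence
          else as.character(dataset)
  d <- length(spec$patterns)
  X <- matrix(0, length(seqs), d,
              dimnames = list(NULL, spec$patterns))
  if (d == 0L) return(X)
  if (spec$kind == "binary_indicator") {
    for (j in seq_len(d))
      X[, j] <- as.numeric(grepl(spec$patterns[j], seqs, fixed = TRUE))
  } else {
    k <- spec$k
    short <- nchar(seqs) < k
    if (any(short))
      warning(sum(short), " sequence(s) shorter than k = ", k,
              "; all-zero feature rows")
    for (i in which(!short)) {
      km <- seq_kmers(seqs[i], k)
      tab <- table(km)
      hit <- intersect(names(tab), spec$patterns)
      X[i, hit] <- as.numeric(tab[hit]) / length(km)
    }
  }
  X
}

#' Train a soft-margin linear SVM
#'
#' Minimizes `0.5 * w'w + C * sum(max(0, 1 - y_i * (w'x_i + b)))` via the
#' C-classification mode of libsvm with a linear kernel (no scaling), and
#' extracts the primal weight vector and intercept oriented so that a
#' positive decision value predicts the +1 class.
#'
#' @param X numeric feature matrix (rows = proteins).
#' @param y labels in {-1, +1}; both classes must be present.
#' @param C hinge-loss trade-off (> 0).
#' @return An object of class `linear_model`: list with `weights` (length
#'   `ncol(X)`), `intercept`, `C`.
#' @export
train_linear_svm <- function(X, y, C = 1) {
  y <- as.integer(y)
  stopifnot(all(y %in% c(-1L, 1L)), nrow(X) == length(y), C > 0)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  fit <- e1071::svm(x = X, y = factor(y, levels = c(1L, -1L)),
                    kernel = "linear", cost = C, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients positive decision values toward whichever class it
  # encountered first; flip so that f > 0 predicts the +1 class
  first_class <- fit$levels[fit$labels[1]]
  if (first_class == "-1") {
    w <- -w
    b <- -b
  }
  structure(list(weights = stats::setNames(as.numeric(w), colnames(X)),
                 intercept = as.numeric(b), C = C),
            class = "linear_model")
}

#' @rdname train_linear_svm
#' @param model a `linear_model`.
#' @return `svm_decision()`: the decision values `X %*% w + b`.
#' @export
svm_decision <- function(model, X) {
  drop(X %*% model$weights + model$intercept)
}

svm_objective <- function(w, b, X, y, C) {
  f <- drop(X %*% w + b)
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * f))
}

#' Classification metrics at a threshold sweep
#'
#' Confusion counts use the convention `score >= theta` predicts +1, with
#' `theta = 0` for F1 and MCC. The ROC curve is the full threshold sweep;
#' AUC is computed by the rank (Mann-Whitney) statistic, which equals the
#' area under the ROC polyline with tied scores traversed diagonally.
#' AUC-10% is the ROC integral over false-positive rates in `[0, 0.1]`
#' multiplied by 10, so a perfect classifier scores 1. MCC is defined as 0
#' when any confusion marginal is zero; AUC is `NA` (with a warning) when
#' the test set contains a single class.
#'
#' @param scores numeric decision values.
#' @param labels labels in {-1, +1}.
#' @return A list with `confusion` (TP, FP, TN, FN at theta = 0), `f1`,
#'   `mcc`, `auc`, `auc10`, and `roc` (data.frame of FPR, TPR).
#' @export
compute_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(-1L, 1L)), length(scores) == length(labels))
  pos <- labels == 1L
  np <- sum(pos)
  nn <- sum(!pos)
  tp <- sum(scores >= 0 & pos)
  fp <- sum(scores >= 0 & !pos)
  tn <- sum(scores < 0 & !pos)
  fn <- sum(scores < 0 & pos)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  if (np == 0L || nn == 0L) {
    warning("single-class test set: AUC undefined")
    auc <- NA_real_
    auc10 <- NA_real_
    roc <- data.frame(fpr = numeric(0), tpr = numeric(0))
  } else {
    r <- rank(scores)
    auc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
    roc <- roc_points(scores, pos)
    auc10 <- 10 * roc_partial_area(roc, 0.1)
  }
  list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       f1 = f1, mcc = mcc, auc = auc, auc10 = auc10, roc = roc)
}

roc_points <- function(scores, pos) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # one vertex per distinct threshold; ties move diagonally
  grp <- cumsum(!duplicated(s))
  ctp <- cumsum(p)
  cfp <- cumsum(!p)
  last <- which(!duplicated(grp, fromLast = TRUE))
  data.frame(fpr = c(0, cfp[last] / sum(!pos)),
             tpr = c(0, ctp[last] / sum(pos)))
}

roc_partial_area <- function(roc, xmax) {
  x <- roc$fpr
  y <- roc$tpr
  area <- 0
  for (i in seq_len(length(x) - 1)) {
    x0 <- x[i]; x1 <- x[i + 1]
    if (x0 >= xmax) break
    y0 <- y[i]; y1 <- y[i + 1]
    if (x1 > xmax) {  # clip the segment at xmax
      y1 <- y0 + (y1 - y0) * (xmax - x0) / (x1 - x0)
      x1 <- xmax
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  area
}

#' Select the SVM trade-off C by inner leave-category-out CV
#'
#' Evaluates a geometric grid `log10(C) = -27/9, -23/9, ..., 9/9` (10
#' values) by leave-category-out cross-validation over the paired categories
#' of the training set, pooling held-out scores across inner folds. When the
#' best C sits on a grid boundary the grid is extended by steps of 4/9 in
#' that direction for as long as the extension strictly improves the best
#' score. Ties are resolved to the smallest C. The feature spec is built
#' once per inner fold from that fold's training categories when
#' `spec_builder` is supplied, otherwise a fixed `spec` is reused.
#'
#' @param dataset training [protein_dataset()] with at least 2 paired
#'   categories.
#' @param spec a fixed [feature_spec()] used for every inner fold.
#' @param metric scoring metric: `"auc"`, `"auc10"`, `"f1"`, or `"mcc"`.
#' @param grid_log10 initial grid of `log10(C)` values.
#' @param max_extensions safety cap on boundary extensions.
#' @return A list with `C`, `log10_C`, and the evaluated `grid`
#'   (data.frame of `log10_C`, `score`).
#' @export
select_C <- function(dataset, spec, metric = c("auc", "auc10", "f1", "mcc"),
                     grid_log10 = seq(-27, 9, by = 4) / 9,
                     max_extensions = 20L) {
  metric <- match.arg(metric)
  prof <- classify_categories(dataset)
  paired <- prof$category[prof$type == "paired"]
  if (length(paired) < 2L) stop("need >= 2 paired categories to select C")
  X <- build_feature_matrix(dataset, spec)
  y <- dataset$label

  score_C <- function(C) {
    sc <- numeric(0)
    lb <- integer(0)
    for (g in paired) {
      te <- dataset$category == g
      if (length(unique(y[!te])) < 2L) next
      m <- train_linear_svm(X[!te, , drop = FALSE], y[!te], C)
      sc <- c(sc, svm_decision(m, X[te, , drop = FALSE]))
      lb <- c(lb, y[te])
    }
    met <- suppressWarnings(compute_metrics(sc, lb))
    met[[metric]]
  }

  grid <- sort(grid_log10)
  scores <- vapply(grid, function(g) score_C(10^g), numeric(1))
  best_at_boundary <- function() {
    b <- grid[which.max(scores)]  # which.max: first max = smallest C
    c(low = b == grid[1], high = b == grid[length(grid)])
  }
  ext <- 0L
  repeat {
    at <- best_at_boundary()
    if (!any(at) || ext >= max_extensions) break
    step <- 4 / 9
    newg <- if (at["low"]) grid[1] - step else grid[length(grid)] + step
    news <- score_C(10^newg)
    improved <- news > max(scores)
    if (at["low"]) {
      grid <- c(newg, grid)
      scores <- c(news, scores)
    } else {
      grid <- c(grid, newg)
      scores <- c(scores, news)
    }
    ext <- ext + 1L
    if (!improved) break
  }
  best <- grid[which.max(scores)]
  list(C = 10^best, log10_C = best,
       grid = data.frame(log10_C = grid, score = scores))
}

#' Mine ASP/non-ASP features from a training set
#'
#' Runs the full discovery chain on the given (training) data: permutation
#' calibration of the adjusted level delta, significant-pattern mining on
#' both enrichment sides, and the ASP / non-ASP screens. The union of the
#' selected patterns defines a binary-indicator feature spec.
#'
#' @param dataset training [protein_dataset()].
#' @param alpha target FWER.
#' @param m_perms number of label permutations.
#' @param seed RNG seed for the permutation plan.
#' @param min_support minimum pattern support.
#' @return A list with `spec` (a [feature_spec()]), `asps`, `non_asps`,
#'   `calibration`.
#' @export
mine_features <- function(dataset, alpha = 0.05, m_perms = 100L, seed,
                          min_support = 1L) {
  plan <- generate_permutations(dataset, m_perms, seed)
  cal <- wy_calibrate(dataset, plan, alpha, min_support)
  prof <- classify_categories(dataset)
  asps <- data.frame()
  nasps <- data.frame()
  if (cal$delta > 0) {
    sig_pos <- find_significant_patterns(dataset, cal$delta, "allergen",
                                         min_support)
    sig_neg <- find_significant_patterns(dataset, cal$delta, "nonallergen",
                                         min_support)
    asps <- select_asps(sig_pos, dataset, prof, cal)
    nasps <- select_non_asps(sig_neg, dataset, prof, cal)
  }
  pats <- unique(c(asps$pattern, nasps$pattern))
  list(spec = feature_spec(pats, "binary_indicator"),
       asps = asps, non_asps = nasps, calibration = cal)
}

#' Leave-category-out cross-validation
#'
#' One fold per paired category: the fold's test set is every protein of
#' that category and the model is trained on all remaining proteins, with
#' the feature set re-derived from the training portion only (for the
#' `"asp"` source this repeats permutation calibration and pattern mining
#' per fold with a fold-specific seed derived from `seed`, so held-out
#' categories never influence feature discovery).
#'
#' @param dataset a [protein_dataset()] with at least 2 paired categories.
#' @param features `"asp"` (mined ASP + non-ASP indicators), `"kmer1"`,
#'   `"kmer2"`, `"kmer6"` (k-mer features), or `"external"` (a precomputed
#'   matrix supplied via `external`).
#' @param alpha,m_perms,min_support mining settings for the `"asp"` source.
#' @param seed master seed; per-fold seeds are derived from it.
#' @param C SVM trade-off: a number, or `"auto"` for inner-CV selection via
#'   [select_C()].
#' @param metric metric used by `"auto"` C selection.
#' @param support_threshold document-frequency threshold for `"kmer6"`.
#' @param external optional numeric matrix (rows aligned with `dataset`)
#'   for `features = "external"`.
#' @return A list with `predictions` (data.frame `id`, `category`, `score`,
#'   `label`), `per_fold` metrics, `pooled` metrics over concatenated
#'   scores, `mean_auc` (mean of the per-fold AUCs), and `fold_features`
#'   (patterns used per fold).
#' @export
leave_category_out_cv <- function(dataset,
                                  features = c("asp", "kmer1", "kmer2",
                                               "kmer6", "external"),
                                  alpha = 0.05, m_perms = 100L, seed = 1L,
                                  min_support = 1L, C = "auto",
                                  metric = "auc", support_threshold = 15L,
                                  external = NULL) {
  features <- match.arg(features)
  prof <- classify_categories(dataset)
  paired <- prof$category[prof$type == "paired"]
  if (length(paired) < 2L)
    stop("leave-category-out CV needs at least 2 paired categories")
  if (features == "external" &&
      (is.null(external) || nrow(external) != nrow(dataset)))
    stop("features = 'external' requires a matrix with one row per protein")

  preds <- list()
  per_fold <- list()
  fold_features <- list()
  for (fi in seq_along(paired)) {
    g <- paired[fi]
    te <- dataset$category == g
    train <- dataset[!te, , drop = FALSE]
    class(train) <- class(dataset)
    spec <- switch(features,
      asp = mine_features(train, alpha, m_perms,
                          seed = derive_seed(seed, fi),
                          min_support = min_support)$spec,
      kmer1 = kmer_feature_spec(train, 1L),
      kmer2 = kmer_feature_spec(train, 2L),
      kmer6 = kmer_feature_spec(train, 6L, support_threshold),
      external = NULL)
    if (features == "external") {
      Xtr <- external[!te, , drop = FALSE]
      Xte <- external[te, , drop = FALSE]
      fold_features[[g]] <- colnames(external)
    } else {
      fold_features[[g]] <- spec$patterns
      Xtr <- build_feature_matrix(train, spec)
      Xte <- build_feature_matrix(dataset[te, "sequence"], spec)
    }
    if (ncol(Xtr) == 0L) {
      sc <- rep(0, sum(te))  # no informative features: uninformative scores
    } else {
      Cf <- C
      if (identical(C, "auto")) {
        # external matrices carry no spec to rebuild per inner fold
        Cf <- if (features == "external") 1 else
          tryCatch(select_C(train, spec, metric = metric)$C,
                   error = function(e) 1)
      }
      model <- train_linear_svm(Xtr, train$label, Cf)
      sc <- svm_decision(model, Xte)
    }
    preds[[g]] <- data.frame(id = dataset$id[te], category = g,
                             score = sc, label = dataset$label[te],
                             stringsAsFactors = FALSE)
    per_fold[[g]] <- suppressWarnings(
      compute_metrics(sc, dataset$label[te]))
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  pooled <- suppressWarnings(
    compute_metrics(predictions$score, predictions$label))
  aucs <- vapply(per_fold, function(m) m$auc, numeric(1))
  list(predictions = predictions, per_fold = per_fold, pooled = pooled,
       mean_auc = mean(aucs, na.rm = TRUE), fold_features = fold_features)
}
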