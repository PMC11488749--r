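#' Greedy pairwise-correlation filter
#'
#' While any pair of numeric predictors has absolute Pearson correlation at
#' or above the cutoff, the member of the worst (most correlated) pair with
#' the larger mean absolute correlation to all other predictors is removed
#' (ties broken lexicographically by column name). Categorical columns pass
#' through untouched; constant columns are dropped with a warning because
#' their correlation is undefined.
#'
#' @param X Predictor data.frame (may include non-numeric columns).
#' @param cutoff Absolute-correlation cutoff in `(0, 1]`.
#' @return List with `table` (filtered data.frame) and `removed`
#'   (character vector of dropped column names, in removal order).
#' @export
correlation_filter <- function(X, cutoff) {
  stopifnot(cutoff > 0, cutoff <= 1)
  num <- names(X)[vapply(X, is.numeric, logical(1))]
  removed <- character(0)
  const <- num[vapply(X[num], function(x) stats::sd(x) == 0, logical(1))]
  if (length(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(const, collapse = ", ")))
    removed <- c(removed, const)
    num <- setdiff(num, const)
  }
  while (length(num) >= 2L) {
    cm <- abs(stats::cor(X[num]))
    diag(cm) <- 0
    if (max(cm) < cutoff) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- sort(colnames(cm)[worst])
    mean_abs <- colMeans(cm)[pair] * length(num) / (length(num) - 1L)
    drop <- if (mean_abs[1] == mean_abs[2]) pair[1L]
            else pair[which.max(mean_abs)]
    removed <- c(removed, drop)
    num <- setdiff(num, drop)
  }
  list(table = X[setdiff(names(X), removed)], removed = removed)
}

#' Stratified train/test split
#'
#' Samples `round(train_frac * n_c)` members of every class into the
#' training set, so class proportions are preserved to within one sample.
#'
#' @param labels Factor or character class labels.
#' @param train_frac Training fraction (default 0.70).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, train_frac = 0.70, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  labels <- as.character(labels)
  if (any(table(labels) < 2L)) stop("every class needs at least 2 members")
  with_seed(seed, {
    train <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_tr <- max(1L, min(length(idx) - 1L, round(train_frac * length(idx))))
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Train the random-forest classifier with repeated cross-validated tuning
#'
#' Tunes `mtry` over a small grid centred on `floor(sqrt(p))` by repeated
#' stratified k-fold cross-validation optimising the area under the ROC
#' curve, then refits a 500-tree forest on the full training set with
#' permutation importance enabled.
#'
#' @param train_table data.frame of predictors plus a `label` column with
#'   values `"hidden"` / `"not_hidden"`; no missing values.
#' @param cv_folds,cv_repeats Cross-validation folds and repeats
#'   (defaults 10 and 5).
#' @param n_trees Trees in the final forest (default 500).
#' @param seed Integer seed.
#' @return List with `model` (the caret fit), `mtry` (chosen value) and
#'   `importance` (data.frame: predictor, MDA, Gini).
#' @export
train_rf <- function(train_table, cv_folds = 10, cv_repeats = 5,
                     n_trees = 500, seed = 1L) {
  stopifnot("label" %in% names(train_table))
  y <- factor(train_table$label, levels = c("hidden", "not_hidden"))
  if (length(unique(y)) < 2L) stop("training set has a single class")
  X <- train_table[setdiff(names(train_table), c("label", "species"))]
  X <- as.data.frame(lapply(X, function(x)
    if (is.character(x)) factor(x) else x))
  p <- ncol(X)
  grid <- data.frame(mtry = sort(unique(pmin(pmax(
    floor(sqrt(p)) + c(-2L, -1L, 0L, 1L, 2L), 1L), p))))
  ctrl <- caret::trainControl(method = "repeatedcv", number = cv_folds,
                              repeats = cv_repeats, classProbs = TRUE,
                              summaryFunction = caret::twoClassSummary)
  fit <- with_seed(seed, caret::train(
    x = X, y = y, method = "rf", metric = "ROC", trControl = ctrl,
    tuneGrid = grid, ntree = n_trees, importance = TRUE))
  imp <- randomForest::importance(fit$finalModel)
  importance <- data.frame(
    predictor = rownames(imp),
    MDA = imp[, "MeanDecreaseAccuracy"],
    Gini = imp[, "MeanDecreaseGini"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(model = fit, mtry = fit$bestTune$mtry, importance = importance)
}

#' Exact one-sided binomial test of accuracy against the no-information rate
#'
#' `P(X >= k | n, nir)`: the probability of at least `k` correct test-set
#' predictions if the classifier only ever guessed the majority class.
#'
#' @param k Correct predictions.
#' @param n Test-set size.
#' @param nir No-information rate (majority-class fraction), in (0, 1).
#' @return The exact upper-tail p-value.
#' @examples
#' binomial_nir_test(20, 24, 0.625)  # 0.02435
#' @export
binomial_nir_test <- function(k, n, nir) {
  stopifnot(k >= 0, k <= n, nir > 0, nir < 1)
  stats::pbinom(k - 1, n, nir, lower.tail = FALSE)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Two-sided exact interval from Beta quantiles; the lower bound is 0 when
#' `k = 0` and the upper bound 1 when `k = n`.
#'
#' @param k Successes.
#' @param n Trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(14, 15)  # (0.6805, 0.9983)
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  stopifnot(k >= 0, k <= n, n >= 1)
  a <- (1 - conf) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Evaluate a trained classifier on a held-out test set
#'
#' Builds the confusion matrix with "hidden" as the positive class and
#' reports accuracy with its exact Clopper-Pearson 95% CI, the test-set
#' no-information rate, the exact binomial p-value of accuracy exceeding it,
#' and the positive/negative predictive values.
#'
#' @param fitted Output of [train_rf()] (or any object whose `model` yields
#'   class predictions via [stats::predict()]).
#' @param test_table data.frame with predictors and a `label` column.
#' @return Object of class `model_report`: list with `confusion` (TP, FP,
#'   FN, TN), `accuracy`, `ci`, `nir`, `p_acc_gt_nir`, `ppv`, `npv`,
#'   `n_test`.
#' @export
evaluate_classifier <- function(fitted, test_table) {
  stopifnot(nrow(test_table) >= 1L)
  truth <- factor(test_table$label, levels = c("hidden", "not_hidden"))
  if (length(unique(truth)) < 2L) stop("test set must contain both classes")
  X <- test_table[setdiff(names(test_table), c("label", "species"))]
  X <- as.data.frame(lapply(X, function(x)
    if (is.character(x)) factor(x) else x))
  pred <- stats::predict(fitted$model, newdata = X)
  pred <- factor(as.character(pred), levels = c("hidden", "not_hidden"))
  tp <- sum(pred == "hidden" & truth == "hidden")
  fp <- sum(pred == "hidden" & truth == "not_hidden")
  fn <- sum(pred == "not_hidden" & truth == "hidden")
  tn <- sum(pred == "not_hidden" & truth == "not_hidden")
  n <- tp + fp + fn + tn
  k <- tp + tn
  nir <- max(table(truth)) / n
  structure(list(
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
    accuracy = k / n,
    ci = clopper_pearson(k, n),
    nir = nir,
    p_acc_gt_nir = binomial_nir_test(k, n, nir),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    n_test = n
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "model_report: accuracy %.4f (95%% CI %.4f-%.4f), NIR %.4f, p[Acc>NIR] %.4g\n",
    x$accuracy, x$ci[1], x$ci[2], x$nir, x$p_acc_gt_nir))
  cat(sprintf("  PPV %.4f, NPV %.4f, n = %d\n", x$ppv, x$npv, x$n_test))
  invisible(x)
}

# predictor kind from its name: SD / mean / geographic / life-history
predictor_kind <- function(x) {
  ifelse(grepl("_sd$", x), "sd",
         ifelse(grepl("_mean$", x) & !grepl("^(lat|lon)_", x), "mean",
                ifelse(grepl("^(lat|lon)_", x), "geographic", "life_history")))
}

#' Rank variable importances and tally predictor kinds
#'
#' For each fitted model, extracts the top-10 predictors by mean decrease in
#' accuracy and by Gini impurity, and tallies what fraction of the pooled
#' top-10 lists are SD-type, mean-type, geographic, or life-history
#' predictors.
#'
#' @param importances List of importance data.frames from [train_rf()]
#'   (columns predictor, MDA, Gini).
#' @param top_n List length (default 10).
#' @return List with `top` (per-model list of `list(MDA =, Gini =)` name
#'   vectors) and `kind_fractions` (named numeric, sums to 1).
#' @export
rank_importance <- function(importances, top_n = 10) {
  stopifnot(length(importances) >= 1L)
  top <- lapply(importances, function(imp) {
    list(MDA = imp$predictor[order(imp$MDA, decreasing = TRUE)][
           seq_len(min(top_n, nrow(imp)))],
         Gini = imp$predictor[order(imp$Gini, decreasing = TRUE)][
           seq_len(min(top_n, nrow(imp)))])
  })
  pooled <- unlist(top, use.names = FALSE)
  kinds <- factor(predictor_kind(pooled),
                  levels = c("sd", "mean", "geographic", "life_history"))
  list(top = top, kind_fractions = prop.table(table(kinds)))
}

#' Kruskal-Wallis comparison of top predictors between classes
#'
#' Runs [stats::kruskal.test()] (rank H statistic with tie correction,
#' chi-squared reference with one degree of freedom for two groups) for each
#' listed predictor and reports the group medians.
#'
#' @param table Predictor table with a `label` column.
#' @param top Character vector of predictor names to test.
#' @return data.frame: predictor, H, p, median_hidden, median_not_hidden.
#' @export
kruskal_wallis_top <- function(table, top) {
  stopifnot(all(top %in% names(table)), "label" %in% names(table))
  g <- factor(table$label)
  out <- lapply(top, function(v) {
    x <- table[[v]]
    if (length(unique(x)) == 1L) {
      H <- 0; p <- 1
    } else {
      kt <- stats::kruskal.test(x, g)
      H <- unname(kt$statistic); p <- kt$p.value
    }
    data.frame(predictor = v, H = H, p = p,
               median_hidden = stats::median(x[g == "hidden"]),
               median_not_hidden = stats::median(x[g == "not_hidden"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
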