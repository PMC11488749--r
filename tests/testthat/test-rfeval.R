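test_that("correlation filter removes the more-connected member of each bad pair", {
  set.seed(2)
  n <- 80
  a <- rnorm(n)
  tab <- data.frame(a = a, b = a + rnorm(n, 0, 0.05), c = rnorm(n))
  # corr(a, b) ~ 1; both correlate ~equally elsewhere: tie -> lexicographic
  f <- correlation_filter(tab, 0.9)
  expect_true(length(f$removed) == 1 && f$removed %in% c("a", "b"))
  cm <- abs(cor(f$table[vapply(f$table, is.numeric, logical(1))]))
  diag(cm) <- 0
  expect_lt(max(cm), 0.9)

  # the member with larger mean |corr| goes: a correlates with both b and d
  tab2 <- data.frame(a = a, b = a + rnorm(n, 0, 0.05),
                     d = a + rnorm(n, 0, 0.8), e = rnorm(n))
  f2 <- correlation_filter(tab2, 0.9)
  expect_identical(f2$removed, "a")

  # nothing above cutoff: unchanged
  tab3 <- data.frame(x = rnorm(n), y = rnorm(n))
  f3 <- correlation_filter(tab3, 0.99)
  expect_identical(f3$table, tab3)
  expect_length(f3$removed, 0)

  # duplicated column at cutoff 1
  tab4 <- data.frame(x = a, y = a, z = rnorm(n))
  f4 <- correlation_filter(tab4, 1)
  expect_length(f4$removed, 1)

  # constant column dropped with warning; categoricals pass through
  tab5 <- data.frame(x = rnorm(n), k = rep(1, n),
                     g = sample(c("u", "v"), n, TRUE))
  expect_warning(f5 <- correlation_filter(tab5, 0.9), "constant")
  expect_identical(f5$removed, "k")
  expect_true("g" %in% names(f5$table))
})

test_that("stratified split preserves class proportions and is deterministic", {
  labels <- rep(c("hidden", "not_hidden"), c(50, 50))
  s <- stratified_split(labels, 0.7, seed = 1)
  expect_length(s$train, 70)
  expect_equal(sum(labels[s$train] == "hidden"), 35)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), seq_along(labels))

  # the published class mix: 51 hidden / 32 not at 70% training
  lab2 <- rep(c("hidden", "not_hidden"), c(51, 32))
  s2 <- stratified_split(lab2, 0.7, seed = 2)
  expect_true(length(s2$test) >= 24 && length(s2$test) <= 26)
  expect_true(all(c("hidden", "not_hidden") %in% lab2[s2$test]))

  expect_identical(stratified_split(labels, 0.7, seed = 9),
                   stratified_split(labels, 0.7, seed = 9))
  expect_error(stratified_split(c("a", "a", "b"), 0.7, 1), "at least 2")
})

test_that("exact binomial NIR p-values match a brute-force tail sum", {
  brute <- function(k, n, p) sum(dbinom(k:n, n, p))
  set.seed(3)
  for (r in 1:40) {
    n <- sample(1:50, 1); k <- sample(0:n, 1); p <- runif(1, 0.05, 0.95)
    expect_equal(binomial_nir_test(k, n, p), brute(k, n, p),
                 tolerance = 1e-6)
  }
  expect_equal(binomial_nir_test(0, 15, 0.8), 1)
})

test_that("Clopper-Pearson intervals match a bisection-on-binomial-CDF oracle", {
  # oracle: invert the exact binomial tails by bisection
  cp_oracle <- function(k, n, conf = 0.95) {
    a <- (1 - conf) / 2
    f_lo <- function(p) 1 - pbinom(k - 1, n, p) - a   # P(X >= k) = a
    f_hi <- function(p) pbinom(k, n, p) - a           # P(X <= k) = a
    lower <- if (k == 0) 0 else uniroot(f_lo, c(1e-12, 1 - 1e-12),
                                        tol = 1e-12)$root
    upper <- if (k == n) 1 else uniroot(f_hi, c(1e-12, 1 - 1e-12),
                                        tol = 1e-12)$root
    c(lower, upper)
  }
  set.seed(4)
  for (r in 1:25) {
    n <- sample(1:50, 1); k <- sample(0:n, 1)
    expect_equal(unname(clopper_pearson(k, n)), cp_oracle(k, n),
                 tolerance = 1e-6)
  }
  expect_equal(unname(clopper_pearson(5, 5))[2], 1)
  expect_equal(unname(clopper_pearson(0, 8))[1], 0)
})

test_that("classifier evaluation reproduces hand-computed confusion statistics", {
  # fixed predictions via a stub model
  stub <- list(model = structure(list(), class = "stub_model"))
  truth <- rep(c("hidden", "not_hidden"), c(17, 7))
  pred <- c(rep("hidden", 15), rep("not_hidden", 2),  # 15 TP, 2 FN
            rep("hidden", 4), rep("not_hidden", 3))   # 4 FP, 3 TN
  registerS3method(
    "predict", "stub_model",
    function(object, ...) factor(pred, c("hidden", "not_hidden")),
    envir = asNamespace("stats"))
  test_tab <- data.frame(x = seq_along(truth), label = truth)
  rep_ <- evaluate_classifier(stub, test_tab)
  expect_equal(unname(rep_$confusion), c(15, 4, 2, 3))
  expect_equal(rep_$accuracy, 0.75)
  expect_equal(rep_$ppv, 15 / 19, tolerance = 1e-9)
  expect_equal(round(rep_$ppv, 4), 0.7895)
  expect_equal(rep_$npv, 0.6)
  expect_equal(rep_$nir, 17 / 24)
  expect_equal(sum(rep_$confusion), rep_$n_test)
  expect_true(rep_$ci[1] <= rep_$accuracy && rep_$accuracy <= rep_$ci[2])
})

test_that("importance ranking tallies predictor kinds correctly", {
  imp <- data.frame(
    predictor = c("annual_precip_sd", "npp_sd", "mean_temp_mean",
                  "lat_length", "body_size", "isothermality_sd",
                  "lon_min", "precip_seasonality_sd", "nuisance_a_mean",
                  "habitat", "nuisance_b_sd", "mean_temp_sd"),
    MDA = 12:1, Gini = 12:1, stringsAsFactors = FALSE)
  rk <- rank_importance(list(imp))
  expect_length(rk$top[[1]]$MDA, 10)
  expect_equal(rk$top[[1]]$MDA[1], "annual_precip_sd")
  expect_equal(sum(rk$kind_fractions), 1)
  expect_equal(unname(rk$kind_fractions["sd"]), 8 / 20)
  expect_equal(unname(rk$kind_fractions["geographic"]), 4 / 20)
  expect_equal(unname(rk$kind_fractions["life_history"]), 4 / 20)
})

test_that("Kruskal-Wallis follow-up matches the base implementation and handles ties", {
  tab <- data.frame(v = c(1, 2, 3, 4, 5, 6),
                    label = rep(c("not_hidden", "hidden"), each = 3))
  kw <- kruskal_wallis_top(tab, "v")
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  ref <- kruskal.test(tab$v, factor(tab$label))
  expect_equal(kw$H, unname(ref$statistic))
  expect_equal(kw$p, ref$p.value)
  expect_equal(kw$median_hidden, 5)
  expect_equal(kw$median_not_hidden, 2)

  flat <- data.frame(v = rep(1, 8), label = rep(c("hidden", "not_hidden"), 4))
  kwf <- kruskal_wallis_top(flat, "v")
  expect_equal(kwf$H, 0)
  expect_equal(kwf$p, 1)
})

test_that("random forest training tunes mtry and yields importances", {
  set.seed(6)
  n <- 60
  x <- rnorm(n)
  tab <- data.frame(f1 = x + rnorm(n, 0, 0.5), f2 = rnorm(n), f3 = rnorm(n),
                    f4 = -x + rnorm(n, 0, 0.5),
                    label = ifelse(x > 0, "hidden", "not_hidden"))
  fit <- train_rf(tab, cv_folds = 3, cv_repeats = 1, n_trees = 100, seed = 2)
  expect_true(fit$mtry >= 1 && fit$mtry <= 4)
  expect_equal(nrow(fit$importance), 4)
  expect_true(all(c("MDA", "Gini") %in% names(fit$importance)))
  split <- stratified_split(tab$label, 0.7, seed = 3)
  rep_ <- evaluate_classifier(fit, tab[split$test, ])
  expect_equal(sum(rep_$confusion), length(split$test))
})
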