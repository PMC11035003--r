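make_classif_table <- function(n = 200, delta = 2, n_noise = 9, seed = 1) {
  set.seed(seed)
  lab <- rep(c("nonresponse", "response"), each = n / 2)
  x <- matrix(rnorm(n * n_noise), n, n_noise)
  colnames(x) <- paste0("noise_", seq_len(n_noise))
  info <- rnorm(n) + ifelse(lab == "nonresponse", delta, 0)
  data.frame(label = factor(lab, levels = c("response", "nonresponse")),
             signal = info, x)
}

test_that("Gini ranking finds an informative feature among noise", {
  hits <- vapply(1:50, function(s) {
    tab <- make_classif_table(seed = s)
    rk <- rank_features_gini(tab, n_trees = 200, k = 1, seed = s)
    rk$ranking[1] == "signal"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  rk <- rank_features_gini(make_classif_table(seed = 1), n_trees = 200,
                           seed = 1)
  expect_equal(sum(rk$importance), 1, tolerance = 1e-9)
  expect_true(all(rk$importance >= 0))
  expect_setequal(rk$ranking, c("signal", paste0("noise_", 1:9)))
  # determinism under a fixed seed
  rk2 <- rank_features_gini(make_classif_table(seed = 1), n_trees = 200,
                            seed = 1)
  expect_identical(rk$importance, rk2$importance)
})

test_that("uninformative labels yield no consistently dominant feature", {
  ranks <- t(vapply(1:50, function(s) {
    tab <- make_classif_table(seed = s, delta = 0)
    rk <- rank_features_gini(tab, n_trees = 100, seed = s)
    match(c("signal", paste0("noise_", 1:9)), rk$ranking)
  }, numeric(10)))
  # Friedman-type check: mean ranks should not distinguish the features
  fr <- stats::friedman.test(ranks)
  expect_gt(fr$p.value, 0.01)
})

test_that("a duplicated informative feature splits but keeps importance", {
  hits <- vapply(1:50, function(s) {
    tab <- make_classif_table(seed = s)
    tab$signal_dup <- tab$signal
    rk <- rank_features_gini(tab, n_trees = 200, seed = s)
    sum(rk$importance[c("signal", "signal_dup")]) >
      max(rk$importance[paste0("noise_", 1:9)])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("TA forest separates separable data and refuses unseen features", {
  tab <- make_classif_table(n = 100, delta = 20, seed = 2)
  fit <- fit_ta_model(tab, features = c("signal", "noise_1"), seed = 2)
  pr <- predict(fit, tab)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(roc_auc(pr, tab$label)$auc, 1.0)
  expect_error(predict(fit, tab[, c("label", "noise_2"), drop = FALSE]),
               "unseen feature")
  expect_error(fit_ta_model(tab, features = "absent"), "absent")
  # identical refit reproduces identical predictions
  fit2 <- fit_ta_model(tab, features = c("signal", "noise_1"), seed = 2)
  expect_identical(predict(fit2, tab), pr)
  # soft-vote probabilities average near training prevalence
  tab2 <- make_classif_table(n = 200, delta = 1, seed = 3)
  f2 <- fit_ta_model(tab2, features = c("signal", "noise_1"), seed = 3)
  expect_lt(abs(mean(predict(f2, tab2)) - 0.5), 0.05)
})

test_that("permuted labels give chance-level out-of-fold AUC", {
  set.seed(9)
  tab <- make_classif_table(n = 200, delta = 2, seed = 9)
  tab$label <- sample(tab$label)
  folds <- sample(rep(1:5, length.out = nrow(tab)))
  oof <- numeric(nrow(tab))
  for (k in 1:5) {
    fit <- fit_ta_model(tab[folds != k, ],
                        features = c("signal", "noise_1", "noise_2"),
                        n_trees = 200, seed = k)
    oof[folds == k] <- predict(fit, tab[folds == k, ])
  }
  expect_lt(abs(roc_auc(oof, tab$label)$auc - 0.5), 0.1)
})

test_that("forward-LR selection keeps associated terms and drops null ones", {
  res <- t(vapply(1:100, function(s) {
    set.seed(s)
    n <- 500
    x1 <- rnorm(n); x2 <- rnorm(n)
    p <- plogis(-0.5 + 2 * x1)
    tab <- data.frame(label = ifelse(runif(n) < p, "nonresponse", "response"),
                      x1 = x1, x2 = x2)
    m <- forward_lr_logistic(tab, c("x1", "x2"))
    c(x1_in = "x1" %in% m$entered, x2_in = "x2" %in% m$entered)
  }, logical(2)))
  expect_equal(mean(res[, "x1_in"]), 1)       # the true signal always enters
  expect_lte(mean(res[, "x2_in"]), 0.10)      # null term enters at ~alpha
})

test_that("forward-LR handles constants, rescaling and separation", {
  set.seed(4)
  tab <- data.frame(label = rep(c("nonresponse", "response"), each = 25),
                    flat = rep(1.7, 50), x = rnorm(50))
  m <- forward_lr_logistic(tab, c("flat"))
  expect_length(m$entered, 0)
  expect_equal(rownames(m$coefficients), "(Intercept)")
  # affine rescaling of candidates does not change the entered set
  set.seed(12)
  n <- 300
  x1 <- rnorm(n)
  tab2 <- data.frame(
    label = ifelse(runif(n) < plogis(1.5 * x1), "nonresponse", "response"),
    x1 = x1, x2 = rnorm(n))
  m1 <- forward_lr_logistic(tab2, c("x1", "x2"))
  tab3 <- tab2; tab3$x1 <- 100 * tab3$x1 - 3; tab3$x2 <- tab3$x2 / 50
  m2 <- forward_lr_logistic(tab3, c("x1", "x2"))
  expect_identical(m1$entered, m2$entered)
  # perfect separation falls back to a penalized fit with a warning
  sep <- data.frame(label = rep(c("nonresponse", "response"), each = 20),
                    x = c(rnorm(20, 10), rnorm(20, -10)))
  expect_warning(ms <- forward_lr_logistic(sep, "x"), "separation")
  expect_true(ms$separation)
  expect_identical(ms$entered, "x")
  expect_true(is.finite(ms$coefficients["x", "Estimate"]))
})

test_that("ADC candidate screening follows two-group significance", {
  set.seed(6)
  n <- 200
  lab <- rep(c("nonresponse", "response"), each = n / 2)
  shift <- ifelse(lab == "nonresponse", 3, 0)
  strong <- data.frame(label = lab,
                       pre_ADC = rnorm(n) + shift,
                       post_ADC = rnorm(n) + shift,
                       ADC_change = rnorm(n) + shift)
  expect_setequal(select_significant_adc_candidates(strong),
                  c("pre_ADC", "post_ADC", "ADC_change"))
  null <- data.frame(label = lab, pre_ADC = rnorm(n),
                     post_ADC = rnorm(n), ADC_change = rnorm(n))
  expect_lte(length(select_significant_adc_candidates(null)), 1)
})
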