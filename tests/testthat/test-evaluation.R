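test_that("ROC handles separable, tied and random scores correctly", {
  lab <- rep(c("nonresponse", "response"), each = 10)
  sep <- c(rnorm(10, 10), rnorm(10, -10))
  r <- roc_auc(sep, lab)
  expect_equal(r$auc, 1.0)
  expect_equal(r$youden$sensitivity, 1.0)
  expect_equal(r$youden$specificity, 1.0)
  tied <- roc_auc(rep(3.3, 20), lab)
  expect_equal(tied$auc, 0.5)
  expect_error(roc_auc(rnorm(5), rep("nonresponse", 5)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic exactly", {
  set.seed(17)
  for (i in 1:100) {
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    lab <- rep(c("nonresponse", "response"), c(n1, n0))
    scores <- sample(1:6, n1 + n0, replace = TRUE)  # force ties
    expect_identical(roc_auc(scores, lab)$auc, u_statistic_auc(scores, lab))
  }
})

test_that("AUC confidence intervals are clipped and contain the estimate", {
  set.seed(8)
  lab <- rep(c("nonresponse", "response"), each = 15)
  r <- roc_auc(rnorm(30) + (lab == "nonresponse"), lab)
  expect_true(r$ci[1] >= 0 && r$ci[2] <= 1)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
})

test_that("binary rater ROC equals (sens + spec) / 2", {
  lab <- rep(c("nonresponse", "response"), c(36, 158))
  calls <- c(rep(1, 10), rep(0, 26), rep(1, 7), rep(0, 151))
  r <- binary_rater_roc(calls, lab)
  expect_equal(r$auc, (10 / 36 + 151 / 158) / 2)
  expect_equal(binary_rater_roc(as.integer(lab == "nonresponse"), lab)$auc, 1)
  expect_error(binary_rater_roc(c(0, 2, 1), c(1, 0, 1)), "binary")
})

test_that("DeLong paired test: identity, antisymmetry and pROC agreement", {
  lab <- rep(c("nonresponse", "response"), each = 10)
  set.seed(3)
  a <- rnorm(20) + 1.2 * (lab == "nonresponse")
  b <- rnorm(20) + 0.4 * (lab == "nonresponse")
  self <- delong_paired_test(a, a, lab)
  expect_equal(self$diff, 0)
  expect_equal(self$p_value, 1)
  d1 <- delong_paired_test(a, b, lab)
  d2 <- delong_paired_test(b, a, lab)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$p_value, d2$p_value)
  # zero-variance limit, unequal AUCs: divergent statistic as in pROC
  perfect <- as.numeric(lab == "nonresponse")
  dd <- delong_paired_test(perfect, rep(0.2, 20), lab)
  expect_equal(dd$z, Inf)
  expect_equal(dd$p_value, 0)
  # independent reference implementation
  pr <- pROC::roc.test(
    pROC::roc(lab, a, levels = c("response", "nonresponse"),
              direction = "<", quiet = TRUE),
    pROC::roc(lab, b, levels = c("response", "nonresponse"),
              direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(d1$p_value, unname(pr$p.value), tolerance = 1e-10)
  expect_equal(roc_auc(a, lab)$var_auc,
               unname(pROC::var(pROC::roc(lab, a,
                 levels = c("response", "nonresponse"),
                 direction = "<", quiet = TRUE), method = "delong")),
               tolerance = 1e-10)
})

test_that("DeLong single-AUC variance approaches Hanley-McNeil for large n", {
  set.seed(44)
  lab <- rep(c("nonresponse", "response"), each = 150)
  scores <- rnorm(300) + (lab == "nonresponse")
  r <- roc_auc(scores, lab)
  a <- r$auc; n1 <- 150; n0 <- 150
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  hm <- (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
    (n1 * n0)
  expect_lt(abs(r$var_auc - hm) / hm, 0.1)
})

test_that("Cohen's kappa matches the hand p_o/p_e formula", {
  a <- c(rep(1, 30), rep(0, 10)); b <- a
  k1 <- cohens_kappa(a, b)
  expect_equal(k1$kappa, 1)
  # independence table [[25,25],[25,25]] -> kappa 0
  a2 <- rep(c(1, 1, 0, 0), each = 25)
  b2 <- rep(c(1, 0, 1, 0), each = 25)
  expect_equal(cohens_kappa(a2, b2)$kappa, 0)
  # frozen oracle for table [[20,5],[10,65]]:
  # p_o = 0.85, p_e = 0.25*0.30 + 0.75*0.70 = 0.60, kappa = 0.625
  a3 <- rep(c(1, 1, 0, 0), c(20, 5, 10, 65))
  b3 <- rep(c(1, 0, 1, 0), c(20, 5, 10, 65))
  k3 <- cohens_kappa(a3, b3)
  expect_equal(k3$kappa, 0.625)
  expect_equal(k3$p_observed, 0.85)
  expect_equal(k3$p_chance, 0.60)
  expect_true(k3$ci[1] <= 0.625 && 0.625 <= k3$ci[2])
  # symmetry in the raters
  expect_equal(cohens_kappa(b3, a3)$kappa, k3$kappa)
  # both raters constant and equal: chance agreement 1, kappa undefined
  kd <- cohens_kappa(rep(1, 10), rep(1, 10))
  expect_true(kd$degenerate)
  expect_true(is.na(kd$kappa))
})

test_that("numeric group comparison picks tests by normality and is sane", {
  lab <- rep(c("nonresponse", "response"), each = 20)
  set.seed(2)
  vals <- rep(1:20, 2)
  r <- compare_groups_numeric(vals, lab)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  norm <- compare_groups_numeric(rnorm(40), lab)
  expect_equal(norm$test, "t")
  skewed <- compare_groups_numeric(rexp(40)^3, lab)
  expect_equal(skewed$test, "mann-whitney")
  expect_error(compare_groups_numeric(rep(1, 40), lab), "constant")
})

test_that("summary t-test flags the published post-treatment mean gap", {
  r <- t_test_from_summary(0.906, 0.269, 36, 1.060, 0.240, 158)
  expect_lt(r$p_value, 0.001)
  expect_equal(r$df, 192)
  # no-difference case
  r0 <- t_test_from_summary(1, 0.2, 30, 1, 0.2, 30)
  expect_equal(r0$p_value, 1)
})

test_that("categorical comparison switches between chi-squared and Fisher", {
  r <- compare_groups_categorical(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$test, "chi-squared")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # small-count table -> Fisher, matched to hypergeometric enumeration
  tab <- matrix(c(1, 9, 9, 1), 2)
  rf <- compare_groups_categorical(tab)
  expect_equal(rf$test, "fisher")
  p_oracle <- sum(vapply(0:10, function(k) {
    p <- stats::dhyper(k, 10, 10, 10)
    if (p <= stats::dhyper(1, 10, 10, 10) + 1e-12) p else 0
  }, numeric(1)))
  expect_equal(rf$p_value, p_oracle, tolerance = 1e-10)
  expect_error(compare_groups_categorical(matrix(c(0, 0, 5, 5), 2)),
               "empty")
  expect_error(compare_groups_categorical(matrix(c(1.5, 2, 3, 4), 2)),
               "integers")
})

test_that("published demographic counts are not significantly imbalanced", {
  gender <- matrix(c(28, 110, 8, 48), 2)  # rows: nonresponse, response
  r <- compare_groups_categorical(gender)
  expect_equal(r$test, "chi-squared")
  expect_gt(r$p_value, 0.05)
})
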