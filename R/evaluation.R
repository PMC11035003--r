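#' ROC analysis with DeLong variance
#'
#' Builds the full ROC curve of a continuous (or binary) score against a
#' binary label, with the nonresponse class as positive. The AUC is the
#' trapezoidal area, which for this construction equals the Mann-Whitney
#' statistic U/(n1*n2) with ties counted 1/2. The variance of the AUC is
#' estimated from DeLong's structural components, giving a Wald 95% CI
#' (clipped to \[0, 1\]). The reported operating point maximizes the Youden
#' index (sensitivity + specificity - 1); ties are broken toward higher
#' specificity.
#'
#' @param scores numeric scores, higher = more suspicious of nonresponse.
#' @param labels binary labels; factor/character with level "nonresponse"
#'   as positive, or 0/1 with 1 positive.
#' @return Object of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `var_auc`, `ci` (length 2), `youden` (list: threshold, sensitivity,
#'   specificity), `n_pos`, `n_neg`, and the structural components
#'   `v_pos`/`v_neg`.
#' @export
roc_auc <- function(scores, labels) {
  lb <- as_binary_labels(labels)
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (length(scores) != length(lb)) stop("scores and labels differ in length")
  x <- scores[lb == 1]   # positives (nonresponse)
  y <- scores[lb == 0]   # negatives (response)
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("both classes must be present")
  # structural components: psi(x_i, y_j) = 1, 1/2, 0
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v_pos <- rowMeans(cmp)   # V10, one per positive
  v_neg <- colMeans(cmp)   # V01, one per negative
  auc <- mean(cmp)
  var_auc <- var_or_zero(v_pos) / m + var_or_zero(v_neg) / n
  se <- sqrt(var_auc)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  # curve over all unique thresholds (predict positive when score >= t)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(x >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(y >= t), numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr); thr <- c(Inf, thr)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(fpr[best])]   # ties -> higher specificity
  structure(
    list(thresholds = thr, tpr = tpr, fpr = fpr,
         auc = auc, var_auc = var_auc, ci = ci,
         youden = list(threshold = thr[best], sensitivity = tpr[best],
                       specificity = 1 - fpr[best]),
         n_pos = m, n_neg = n, v_pos = v_pos, v_neg = v_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  cat(sprintf("Youden point: sens %.3f, spec %.3f at threshold %.4g\n",
              x$youden$sensitivity, x$youden$specificity, x$youden$threshold))
  invisible(x)
}

#' ROC of a binary rater
#'
#' A binary call vector defines a two-point ROC whose trapezoidal AUC is
#' (sensitivity + specificity) / 2 — the standard way to place a
#' subjective yes/no reading on the AUC scale.
#'
#' @param calls 0/1 calls (1 = called nonresponse).
#' @inheritParams roc_auc
#' @return A `roc_result`.
#' @export
binary_rater_roc <- function(calls, labels) {
  if (!all(calls %in% c(0, 1))) stop("calls must be binary 0/1")
  roc_auc(as.numeric(calls), labels)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same subjects
#' using the covariance of their DeLong structural components:
#' z = (AUC_A - AUC_B) / sqrt(V_A + V_B - 2 Cov), two-sided normal p.
#' When the estimated variance of the difference is zero the test follows
#' reference implementations: equal AUCs give z = 0, p = 1; unequal AUCs
#' (a perfect separator against a constant score) give a divergent z and
#' p = 0.
#'
#' @param scores_a,scores_b the two score vectors (same subjects, same
#'   order).
#' @inheritParams roc_auc
#' @return list: `auc_a`, `auc_b`, `diff`, `var_diff`, `cov`, `z`,
#'   `p_value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must cover the same subjects")
  ra <- roc_auc(scores_a, labels)
  rb <- roc_auc(scores_b, labels)
  m <- ra$n_pos; n <- ra$n_neg
  cov_ab <- cov_or_zero(ra$v_pos, rb$v_pos) / m +
    cov_or_zero(ra$v_neg, rb$v_neg) / n
  var_diff <- ra$var_auc + rb$var_auc - 2 * cov_ab
  d <- ra$auc - rb$auc
  if (var_diff <= 0) {
    # zero estimated variance: equal AUCs give the null result; unequal
    # AUCs (e.g. a perfect separator vs a constant score) give a divergent
    # statistic, matching reference DeLong implementations
    if (abs(d) < 1e-12) {
      z <- 0; p <- 1
    } else {
      z <- sign(d) * Inf; p <- 0
    }
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ra$auc, auc_b = rb$auc, diff = d,
       var_diff = var_diff, cov = cov_ab, z = z, p_value = p)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e) with the
#' Fleiss-Cohen-Everitt large-sample standard error and a Wald 95% CI.
#'
#' @param calls_a,calls_b binary (or categorical) call vectors over the
#'   same subjects.
#' @return list: `kappa`, `se`, `ci`, `p_observed`, `p_chance`, `table`.
#'   If both raters are constant and identical, chance agreement is 1 and
#'   kappa is undefined: `kappa = NA` with `degenerate = TRUE`.
#' @export
cohens_kappa <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b))
    stop("call vectors must cover the same subjects")
  lev <- sort(unique(c(calls_a, calls_b)))
  a <- factor(calls_a, levels = lev)
  b <- factor(calls_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  po <- sum(diag(p))
  rowm <- rowSums(p); colm <- colSums(p)
  pe <- sum(rowm * colm)
  if (1 - pe < 1e-12)
    return(list(kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                p_observed = po, p_chance = pe, table = tab,
                degenerate = TRUE))
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance
  k <- length(lev)
  A <- 0
  for (i in seq_len(k))
    A <- A + p[i, i] * ((1 - pe) - (colm[i] + rowm[i]) * (1 - po))^2
  B <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    B <- B + p[i, j] * (colm[i] + rowm[j])^2
  B <- B * (1 - po)^2
  C <- (po * pe - 2 * pe + po)^2
  var_k <- (A + B - C) / (n * (1 - pe)^4)
  se <- sqrt(max(var_k, 0))
  ci <- kappa + c(-1, 1) * stats::qnorm(0.975) * se
  list(kappa = as.numeric(kappa), se = se, ci = as.numeric(ci),
       p_observed = as.numeric(po), p_chance = as.numeric(pe),
       table = tab, degenerate = FALSE)
}

#' Two-group comparison of a continuous feature
#'
#' Applies the conventional clinical-table rule: Shapiro-Wilk normality in
#' each group at alpha = 0.05; if both groups look normal, Student's t-test
#' (pooled variance by default, Welch by `welch = TRUE`), otherwise the
#' Mann-Whitney U (Wilcoxon rank-sum) test. Groups smaller than 3 cannot be
#' tested for normality and fall through to Mann-Whitney.
#'
#' @param values numeric vector.
#' @param labels binary group labels (see [roc_auc]).
#' @param welch use the Welch t-test when the t-branch is chosen.
#' @param alpha_normality Shapiro-Wilk significance level.
#' @return list: `test` ("t" or "mann-whitney"), `statistic`, `p_value`.
#' @export
compare_groups_numeric <- function(values, labels, welch = FALSE,
                                   alpha_normality = 0.05) {
  lb <- as_binary_labels(labels)
  g1 <- values[lb == 1]; g0 <- values[lb == 0]
  if (length(g1) < 2 || length(g0) < 2) stop("both groups need n >= 2")
  if (stats::var(g1) == 0 && stats::var(g0) == 0)
    stop("constant values in both groups")
  normal <- function(v) {
    if (length(v) < 3 || length(v) > 5000 || stats::var(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha_normality
  }
  if (normal(g1) && normal(g0)) {
    tt <- stats::t.test(g1, g0, var.equal = !welch)
    list(test = "t", statistic = unname(tt$statistic), p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(g1, g0, exact = FALSE,
                                              correct = FALSE))
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         p_value = wt$p.value)
  }
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sided t-test computed directly from group means,
#' SDs and sizes — the form needed to check published group tables without
#' per-patient data.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df))
}

#' Two-group comparison of a categorical variable
#'
#' Chi-squared test without continuity correction when the sample is large
#' enough for the asymptotic test (total n >= 40 and every expected cell
#' count >= 5), otherwise Fisher's exact test (exact enumeration for 2xk
#' tables).
#'
#' @param tab 2 x k matrix of non-negative integer counts (groups in
#'   rows).
#' @param correct apply the Yates continuity correction in the chi-squared
#'   branch.
#' @return list: `test` ("chi-squared" or "fisher"), `statistic` (NA for
#'   Fisher), `p_value`.
#' @export
compare_groups_categorical <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty row or column in contingency table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (sum(tab) >= 40 && all(expected >= 5)) {
    ct <- stats::chisq.test(tab, correct = correct)
    list(test = "chi-squared", statistic = unname(ct$statistic),
         p_value = ct$p.value)
  } else {
    ft <- stats::fisher.test(tab)
    list(test = "fisher", statistic = NA_real_, p_value = ft$p.value)
  }
}

# ---- helpers ----

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("nonresponse", "response"))
    if (length(bad))
      stop("unknown labels: ", paste(bad, collapse = ", "))
    return(as.integer(labels == "nonresponse"))
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1 or response/nonresponse")
  as.integer(labels)
}

var_or_zero <- function(x) if (length(x) < 2) 0 else stats::var(x)

cov_or_zero <- function(x, y) if (length(x) < 2) 0 else stats::cov(x, y)
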