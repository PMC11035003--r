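#' Intraclass correlation for two raters, absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC —
#' ICC(2,1) in the Shrout-Fleiss taxonomy — the standard choice when two
#' readers each measure every subject once and systematic reader offsets
#' should count against agreement. From the two-way ANOVA mean squares with
#' n subjects and k = 2 raters:
#'
#' ICC = (MS_R - MS_E) / (MS_R + MS_E + (2/n) (MS_C - MS_E))
#'
#' where MS_R, MS_C, MS_E are the subject, rater and residual mean squares.
#' A consistency variant (offsets ignored) is available via `type`.
#'
#' @param ratings numeric matrix, subjects x 2 raters, no missing cells.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return list: `icc`, `type`, and the variance components
#'   `ms_subject`, `ms_rater`, `ms_error`.
#' @export
icc_absolute_single <- function(ratings, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (k != 2) stop("exactly 2 raters required")
  if (n < 3) stop("at least 3 subjects required")
  if (anyNA(ratings)) stop("missing cells in ratings")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total < 1e-24) stop("degenerate ratings: zero total variance")
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  icc <- if (type == "agreement") {
    (ms_r - ms_e) / (ms_r + ms_e + (k / n) * (ms_c - ms_e))
  } else {
    (ms_r - ms_e) / (ms_r + ms_e)
  }
  list(icc = icc, type = type,
       ms_subject = ms_r, ms_rater = ms_c, ms_error = ms_e)
}

#' Inter-reader ICC report over a feature table pair
#'
#' Computes the ICC of every shared numeric feature between two readers'
#' feature tables (same patients, same order) and flags features passing
#' the reproducibility threshold.
#'
#' @param features_r1,features_r2 per-reader feature `data.frame`s as from
#'   [extract_features()].
#' @param features which columns to assess; defaults to the 18 texture
#'   features.
#' @param threshold retain features with ICC strictly above this value.
#' @param type ICC variant, see [icc_absolute_single()].
#' @return `data.frame`: `feature`, `icc`, `keep`.
#' @export
icc_report <- function(features_r1, features_r2,
                       features = texture_feature_names(),
                       threshold = 0.75,
                       type = c("agreement", "consistency")) {
  type <- match.arg(type)
  stopifnot(nrow(features_r1) == nrow(features_r2))
  icc <- vapply(features, function(f) {
    icc_absolute_single(cbind(features_r1[[f]], features_r2[[f]]),
                        type = type)$icc
  }, numeric(1))
  data.frame(feature = features, icc = unname(icc),
             keep = unname(icc > threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter features by reproducibility
#'
#' Retains, in input order, exactly the features whose ICC strictly exceeds
#' the threshold (an ICC equal to the threshold is dropped).
#'
#' @param report an ICC report (`data.frame` with `feature` and `icc`).
#' @param threshold reproducibility cutoff.
#' @return Character vector of retained feature names.
#' @export
filter_features <- function(report, threshold = 0.75) {
  report$feature[report$icc > threshold]
}
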