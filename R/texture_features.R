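#' First-order texture statistics of an ROI intensity sample
#'
#' Computes the six first-order (histogram) features used throughout the
#' package: mean, standard deviation, variance, skewness, excess kurtosis and
#' histogram entropy. Units follow the reporting convention of clinical ADC
#' texture work:
#'
#' * `mean` in 10^-3 mm^2/s (the native pixel scale);
#' * `sd` in 10^-5 mm^2/s, i.e. the raw standard deviation times 100;
#' * `variance` is the square of the reported SD, in (10^-5 mm^2/s)^2;
#' * `skewness` = m3 / m2^1.5 and `kurtosis` = m4 / m2^2 - 3 using population
#'   (biased) central moments, so a normal sample has both near 0;
#' * `entropy` = sum(p * log2(p)) over a 256-bin histogram of the values
#'   min-max scaled to \[0, 255\] (empty bins contribute 0). Note the sign:
#'   this is the negative of Shannon entropy, so values lie in
#'   \[-log2(256), 0\].
#'
#' A constant sample is degenerate: SD, variance and entropy are 0, and
#' skewness/kurtosis are returned as 0 with `degenerate = TRUE` rather than
#' propagating 0/0.
#'
#' @param values numeric vector of at least 2 ROI pixel values
#'   (10^-3 mm^2/s).
#' @param n_bins number of histogram bins for the entropy term.
#' @return Named list: `mean`, `sd`, `variance`, `skewness`, `kurtosis`,
#'   `entropy`, `degenerate`.
#' @examples
#' first_order_stats(c(1, 2, 3, 4))
#' @export
first_order_stats <- function(values, n_bins = 256) {
  if (length(values) < 2) stop("need at least 2 values")
  if (!all(is.finite(values))) stop("non-finite values in ROI")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  if (m2 <= 0) {
    return(list(mean = mu, sd = 0, variance = 0, skewness = 0, kurtosis = 0,
                entropy = 0, degenerate = TRUE))
  }
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  sd_rep <- sqrt(m2) * 100          # 10^-3 -> 10^-5 mm^2/s
  list(
    mean = mu,
    sd = sd_rep,
    variance = sd_rep^2,
    skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2 - 3,
    entropy = histogram_entropy(values, n_bins = n_bins),
    degenerate = FALSE
  )
}

# Signed histogram entropy: sum(p log2 p) over n_bins after per-ROI min-max
# scaling. Left-closed/right-open bins; the maximum value falls in the last
# bin. Zero-width range occupies a single bin -> entropy 0.
histogram_entropy <- function(values, n_bins = 256) {
  rng <- range(values)
  if (rng[2] <= rng[1]) return(0)
  idx <- floor((values - rng[1]) / (rng[2] - rng[1]) * n_bins)
  idx[idx >= n_bins] <- n_bins - 1L
  p <- tabulate(idx + 1L, nbins = n_bins) / length(values)
  p <- p[p > 0]
  sum(p * log2(p))
}

#' Manual mean ADC of an ROI
#'
#' Arithmetic mean of the masked pixel values, emulating the manual ADC
#' measurement a radiologist reads off a workstation ROI.
#'
#' @inheritParams masked_pixels
#' @return Mean ADC (10^-3 mm^2/s).
#' @export
mean_adc <- function(map, mask) mean(masked_pixels(map, mask))

#' Combine dual-reader ADC measurements
#'
#' The study-grade manual ADC is the average of two radiologists'
#' independent measurements; there is deliberately no single-reader
#' fallback, so a missing value is an error.
#'
#' @param adc_reader1,adc_reader2 per-reader mean ADC values
#'   (10^-3 mm^2/s).
#' @return Averaged ADC value.
#' @export
average_reader_adc <- function(adc_reader1, adc_reader2) {
  if (length(adc_reader1) != length(adc_reader2))
    stop("reader ADC vectors differ in length")
  if (anyNA(adc_reader1) || anyNA(adc_reader2))
    stop("missing reader ADC value; both readers are required")
  (adc_reader1 + adc_reader2) / 2
}

#' @param pre_adc,post_adc averaged ADC at each timepoint.
#' @rdname average_reader_adc
#' @export
adc_change <- function(pre_adc, post_adc) post_adc - pre_adc

# Canonical feature order used in every table this package writes.
texture_feature_names <- function() {
  stats6 <- c("mean", "variance", "skewness", "kurtosis", "entropy", "SD")
  as.vector(vapply(stats6, function(s)
    c(paste0("pre_", s), paste0("post_", s), paste0(s, "_change")),
    character(3)))
}

adc_feature_names <- function() c("pre_ADC", "post_ADC", "ADC_change")

all_feature_names <- function() c(adc_feature_names(), texture_feature_names())

#' Per-patient texture feature vector
#'
#' Computes the six first-order statistics at both timepoints plus their
#' changes (change = post - pre for every statistic), yielding the 18
#' texture features of the response-prediction model.
#'
#' @param pre_map,post_map [adc_map]s for the two timepoints.
#' @param pre_mask,post_mask matching [roi_mask]s.
#' @param n_bins histogram bins for entropy.
#' @return Named numeric vector of 18 features
#'   (`pre_mean` ... `SD_change`).
#' @export
compute_feature_vector <- function(pre_map, pre_mask, post_map, post_mask,
                                   n_bins = 256) {
  pre <- first_order_stats(masked_pixels(pre_map, pre_mask), n_bins = n_bins)
  post <- first_order_stats(masked_pixels(post_map, post_mask), n_bins = n_bins)
  out <- numeric(0)
  for (s in c("mean", "variance", "skewness", "kurtosis", "entropy")) {
    out[paste0("pre_", s)] <- pre[[s]]
    out[paste0("post_", s)] <- post[[s]]
    out[paste0(s, "_change")] <- post[[s]] - pre[[s]]
  }
  out["pre_SD"] <- pre$sd
  out["post_SD"] <- post$sd
  out["SD_change"] <- post$sd - pre$sd
  out[texture_feature_names()]
}

#' Extract the full feature table from a cohort
#'
#' Runs texture extraction (consensus reader-1 masks) and dual-reader manual
#' ADC measurement over every patient of a cohort, producing the per-patient
#' feature table consumed by the models: 3 ADC features, 18 texture
#' features, the binary response label and the cohort assignment.
#'
#' @param cohort a cohort list as produced by [generate_cohort()] (or
#'   assembled from [read_adc_image()] calls with the same structure).
#' @param reader which reader's masks drive texture extraction
#'   (`"reader1"` or `"reader2"`); manual ADC always averages both readers.
#' @param n_bins histogram bins for entropy.
#' @return `data.frame` with columns `patient_id`, `cohort`, `label`
#'   (factor nonresponse/response), `pre_ADC`, `post_ADC`, `ADC_change`,
#'   and the 18 texture features.
#' @export
extract_features <- function(cohort, reader = c("reader1", "reader2"),
                             n_bins = 256) {
  reader <- match.arg(reader)
  mask_field <- if (reader == "reader1") "mask" else "mask_reader2"
  rows <- lapply(cohort$patients, function(p) {
    pre_mask <- p$pre[[mask_field]]
    post_mask <- p$post[[mask_field]]
    tex <- compute_feature_vector(p$pre$image, pre_mask,
                                  p$post$image, post_mask, n_bins = n_bins)
    pre_adc <- average_reader_adc(mean_adc(p$pre$image, p$pre$mask),
                                 mean_adc(p$pre$image, p$pre$mask_reader2))
    post_adc <- average_reader_adc(mean_adc(p$post$image, p$post$mask),
                                  mean_adc(p$post$image, p$post$mask_reader2))
    c(pre_ADC = pre_adc, post_ADC = post_adc,
      ADC_change = adc_change(pre_adc, post_adc), tex)
  })
  feat <- do.call(rbind, rows)
  out <- data.frame(
    patient_id = vapply(cohort$patients, `[[`, character(1), "patient_id"),
    cohort = vapply(cohort$patients, `[[`, character(1), "cohort"),
    label = factor(vapply(cohort$patients, `[[`, character(1), "group"),
                   levels = c("response", "nonresponse")),
    feat,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}
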