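#' Default group-level feature targets for a simulated NCT cohort
#'
#' Group means and standard deviations of the targeted first-order features
#' (ROI mean, SD, skewness, excess kurtosis; pre-treatment level and
#' pre-to-post change) for the two response classes of a locally advanced
#' rectal cancer cohort treated with neoadjuvant chemotherapy. These defaults
#' encode the characteristic pattern of such cohorts: non-responders show a
#' slight post-treatment ADC decrease while responders increase, with
#' broadly overlapping dispersion, so group separation at the single-feature
#' level is modest.
#'
#' Units: mean in 10^-3 mm^2/s; SD in 10^-5 mm^2/s; skewness and excess
#' kurtosis unitless. Post-treatment targets are constructed downstream as
#' pre + change, so the change rows are the primitive quantities.
#'
#' @return `data.frame` with columns `feature`, `nonresponse_mean`,
#'   `nonresponse_sd`, `response_mean`, `response_sd`.
#' @export
default_feature_targets <- function() {
  data.frame(
    feature = c("pre_mean", "mean_change",
                "pre_SD", "SD_change",
                "pre_skewness", "skewness_change",
                "pre_kurtosis", "kurtosis_change"),
    nonresponse_mean = c(0.962, -0.056, 12.081, 0.733,
                         0.946, -0.541, 1.685, -0.552),
    nonresponse_sd = c(0.229, 0.125, 2.208, 2.494,
                       0.715, 1.238, 2.922, 3.741),
    response_mean = c(1.030, 0.030, 12.560, 1.440,
                      0.811, -0.518, 1.104, -0.779),
    response_sd = c(0.221, 0.177, 2.279, 2.821,
                    0.687, 0.913, 2.117, 2.229),
    stringsAsFactors = FALSE
  )
}

#' Reference group summary statistics for the full feature panel
#'
#' Published-scale group means and SDs for all 21 features (3 manual ADC +
#' 18 texture) in the two response classes, used for arithmetic consistency
#' checks and report comparisons. The change rows equal post minus pre
#' exactly at the group-mean level.
#'
#' @return `data.frame` with columns `feature`, `nonresponse_mean`,
#'   `nonresponse_sd`, `response_mean`, `response_sd`.
#' @export
reference_group_stats <- function() {
  df <- data.frame(matrix(ncol = 5, nrow = 0))
  rows <- list(
    c("pre_ADC", 0.961, 0.229, 1.018, 0.236),
    c("post_ADC", 0.947, 0.283, 1.043, 0.256),
    c("ADC_change", -0.014, 0.220, 0.025, 0.190),
    c("pre_mean", 0.962, 0.229, 1.030, 0.221),
    c("post_mean", 0.906, 0.269, 1.060, 0.240),
    c("mean_change", -0.056, 0.125, 0.030, 0.177),
    c("pre_variance", 150.680, 52.904, 162.902, 58.214),
    c("post_variance", 169.219, 55.712, 201.836, 73.256),
    c("variance_change", 18.540, 57.628, 38.934, 80.590),
    c("pre_skewness", 0.946, 0.715, 0.811, 0.687),
    c("post_skewness", 0.405, 0.873, 0.293, 0.690),
    c("skewness_change", -0.541, 1.238, -0.518, 0.913),
    c("pre_kurtosis", 1.685, 2.922, 1.104, 2.117),
    c("post_kurtosis", 1.133, 3.212, 0.325, 1.233),
    c("kurtosis_change", -0.552, 3.741, -0.779, 2.229),
    c("pre_entropy", -5.108, 0.302, -5.071, 0.309),
    c("post_entropy", -5.054, 0.273, -4.828, 0.463),
    c("entropy_change", 0.054, 0.392, 0.244, 0.529),
    c("pre_SD", 12.081, 2.208, 12.560, 2.279),
    c("post_SD", 12.813, 2.277, 14.000, 2.425),
    c("SD_change", 0.733, 2.494, 1.440, 2.821)
  )
  data.frame(
    feature = vapply(rows, `[[`, character(1), 1),
    nonresponse_mean = as.numeric(vapply(rows, `[[`, character(1), 2)),
    nonresponse_sd = as.numeric(vapply(rows, `[[`, character(1), 3)),
    response_mean = as.numeric(vapply(rows, `[[`, character(1), 4)),
    response_sd = as.numeric(vapply(rows, `[[`, character(1), 5)),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' Bundles everything the generator needs: group sizes, per-group feature
#' targets, the between-feature correlation used to disaggregate group-level
#' summaries into per-patient targets, ROI geometry, the reader-2 boundary
#' jitter and the operating points of the simulated subjective readers.
#'
#' @param n_nonresponse,n_response group sizes (each >= 2).
#' @param feature_targets per-group target table as in
#'   [default_feature_targets()].
#' @param rho exchangeable correlation between targeted features (a single
#'   number), or a full correlation matrix over the targeted features. The
#'   default 0.3 reflects the mild positive dependence expected between
#'   histogram statistics of the same ROI; independence would understate the
#'   separation a multivariate model can attain.
#' @param roi_shape image dimensions in pixels (the ROI is an inscribed
#'   ellipse with patient-specific radii).
#' @param reader2_mask_jitter fractional boundary perturbation of the
#'   second reader's mask in \[0, 0.5); 0 means identical masks.
#' @param reader_sens,reader_spec sensitivity/specificity of each simulated
#'   subjective reader (vectors, one entry per reader).
#' @param seed integer seed; every random element of the cohort derives
#'   from it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_nonresponse = 36, n_response = 158,
                          feature_targets = default_feature_targets(),
                          rho = 0.3,
                          roi_shape = c(64, 64),
                          reader2_mask_jitter = 0.05,
                          reader_sens = c(0.278, 0.306),
                          reader_spec = c(0.956, 0.949),
                          seed = 1L) {
  if (n_nonresponse < 2 || n_response < 2)
    stop("each group needs at least 2 patients")
  req <- c("feature", "nonresponse_mean", "nonresponse_sd",
           "response_mean", "response_sd")
  if (!all(req %in% names(feature_targets)))
    stop("feature_targets missing columns: ",
         paste(setdiff(req, names(feature_targets)), collapse = ", "))
  if (any(feature_targets$nonresponse_sd < 0) ||
      any(feature_targets$response_sd < 0))
    stop("target SDs must be non-negative")
  p <- nrow(feature_targets)
  if (is.matrix(rho)) {
    corr <- rho
    if (!isTRUE(all.equal(corr, t(corr))) ||
        !isTRUE(all.equal(unname(diag(corr)), rep(1, p))))
      stop("correlation matrix must be symmetric with unit diagonal")
  } else {
    corr <- matrix(rho, p, p)
    diag(corr) <- 1
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9)
    stop(sprintf("correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
                 min(ev)))
  if (reader2_mask_jitter < 0 || reader2_mask_jitter >= 0.5)
    stop("reader2_mask_jitter must lie in [0, 0.5)")
  if (any(reader_sens < 0 | reader_sens > 1) ||
      any(reader_spec < 0 | reader_spec > 1))
    stop("reader sensitivities/specificities must lie in [0, 1]")
  structure(
    list(n_nonresponse = as.integer(n_nonresponse),
         n_response = as.integer(n_response),
         feature_targets = feature_targets,
         correlation = corr,
         roi_shape = as.integer(roi_shape),
         reader2_mask_jitter = reader2_mask_jitter,
         reader_sens = reader_sens, reader_spec = reader_spec,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Feasible (skewness, excess kurtosis) region of the cubic-polynomial
# transform of a standard normal. The classical lower boundary is
# approximately k >= 1.641 s^2 - 1.226; a safety margin keeps the moment
# solver away from the edge where the system becomes ill-conditioned.
cubic_kurtosis_floor <- function(skew, margin = 0.1) {
  1.6410373 * skew^2 - 1.2264489 + margin
}

#' Project (skewness, kurtosis) targets onto the attainable region
#'
#' The cubic moment-matching transform cannot reach every
#' (skewness, excess kurtosis) pair; infeasible targets are replaced by the
#' nearest point (Euclidean, in the unitless skew/kurtosis plane) on the
#' attainable boundary.
#'
#' @param skew,kurt target skewness and excess kurtosis.
#' @return list with `skew`, `kurt`, `moved` (logical).
#' @export
project_feasible_moments <- function(skew, kurt) {
  floor_k <- cubic_kurtosis_floor(skew)
  if (kurt >= floor_k) return(list(skew = skew, kurt = kurt, moved = FALSE))
  # nearest point on the parabola k = f(s): 1-D minimisation over s
  obj <- function(s) (s - skew)^2 + (cubic_kurtosis_floor(s) - kurt)^2
  opt <- stats::optimize(obj, interval = c(skew - 5, skew + 5), tol = 1e-10)
  s_star <- opt$minimum
  list(skew = s_star, kurt = cubic_kurtosis_floor(s_star), moved = TRUE)
}

#' Disaggregate group summaries into per-patient feature targets
#'
#' Draws one target vector per patient from a correlated multivariate normal
#' whose per-feature means and SDs are the configured group values, then
#' enforces per-timepoint feasibility: SD targets are clamped strictly
#' positive and (skewness, kurtosis) pairs are projected onto the region the
#' pixel synthesizer can realize. Post-treatment targets are pre + change by
#' construction.
#'
#' @param config a [cohort_config].
#' @return `data.frame`, one row per patient: `patient_id`, `group`, and
#'   for each timepoint `pre`/`post` the columns `*_mean`, `*_SD` (reported
#'   units, 10^-5 mm^2/s), `*_skewness`, `*_kurtosis`.
#' @export
sample_feature_targets <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ft <- config$feature_targets
  p <- nrow(ft)
  # Cholesky-type factor via eigendecomposition (tolerates PSD matrices)
  ed <- eigen(config$correlation, symmetric = TRUE)
  rot <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), p)
  draw_group <- function(n, group) {
    z <- matrix(stats::rnorm(n * p), n, p) %*% t(rot)
    mu <- ft[[paste0(group, "_mean")]]
    sd <- ft[[paste0(group, "_sd")]]
    x <- sweep(sweep(z, 2, sd, `*`), 2, mu, `+`)
    colnames(x) <- ft$feature
    x
  }
  raw <- rbind(draw_group(config$n_nonresponse, "nonresponse"),
               draw_group(config$n_response, "response"))
  group <- c(rep("nonresponse", config$n_nonresponse),
             rep("response", config$n_response))
  n_tot <- nrow(raw)
  out <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n_tot)),
    group = group,
    stringsAsFactors = FALSE
  )
  get <- function(col) raw[, col]
  for (tp in c("pre", "post")) {
    delta <- if (tp == "pre") 0 else 1
    m  <- get("pre_mean")     + delta * get("mean_change")
    s  <- get("pre_SD")       + delta * get("SD_change")
    sk <- get("pre_skewness") + delta * get("skewness_change")
    ku <- get("pre_kurtosis") + delta * get("kurtosis_change")
    # feasibility: SD strictly positive, mean positive, moments attainable
    s <- pmax(s, 1)        # >= 1e-5 mm^2/s in reported units
    m <- pmax(m, 0.05)
    proj <- mapply(function(a, b) {
      pr <- project_feasible_moments(a, b)
      c(pr$skew, pr$kurt)
    }, sk, ku)
    out[[paste0(tp, "_mean")]] <- m
    out[[paste0(tp, "_SD")]] <- s
    out[[paste0(tp, "_skewness")]] <- proj[1, ]
    out[[paste0(tp, "_kurtosis")]] <- proj[2, ]
  }
  out
}

# Fit y = z + c z^2 + d z^3 so that the *empirical* skewness and excess
# kurtosis of y over the supplied normal draw z match the targets; mean and
# SD are fixed exactly afterwards by affine standardization (skew/kurt are
# affine-invariant). Returns the standardized vector, or NULL on failure.
fit_cubic_sample <- function(z, skew, kurt, tol = 1e-3) {
  z2 <- z^2; z3 <- z^3
  shape_err <- function(par) {
    y <- z + par[1] * z2 + par[2] * z3
    m <- mean(y); yc <- y - m
    m2 <- mean(yc^2)
    if (m2 <= 0) return(1e6)
    sk <- mean(yc^3) / m2^1.5
    ku <- mean(yc^4) / m2^2 - 3
    (sk - skew)^2 + (ku - kurt)^2
  }
  starts <- list(c(skew / 6, kurt / 100), c(0, 0),
                 c(skew / 4, 0.02), c(skew / 8, -0.01))
  best <- NULL
  for (st in starts) {
    opt <- stats::optim(st, shape_err, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$value < (tol / 10)^2) break
  }
  if (best$value > tol^2) return(NULL)
  y <- z + best$par[1] * z2 + best$par[2] * z3
  out <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  attr(out, "coef") <- best$par
  out
}

#' Synthesize masked pixel values with prescribed moments
#'
#' Draws standard normal noise and passes it through a cubic polynomial
#' whose coefficients are solved so the empirical mean, SD, skewness and
#' excess kurtosis of the sample hit the targets. Mean and SD are matched
#' exactly (affine step); skewness and kurtosis to the solver tolerance.
#'
#' @param n number of pixels.
#' @param mean_t target mean (10^-3 mm^2/s).
#' @param sd_t target SD in reported units (10^-5 mm^2/s).
#' @param skew_t,kurt_t target skewness and excess kurtosis.
#' @param max_retries fresh noise draws attempted before giving up.
#' @param require_positive if `TRUE`, draws whose realized sample contains
#'   non-positive values are rejected and redrawn (ADC tumor pixels are
#'   physically strictly positive); if no positive draw is found within the
#'   retry budget the best draw is returned as-is.
#' @return numeric vector of length `n`.
#' @export
synthesize_values <- function(n, mean_t, sd_t, skew_t, kurt_t,
                              max_retries = 8, require_positive = FALSE) {
  sd_raw <- sd_t / 100   # back to 10^-3 mm^2/s pixel scale
  if (sd_raw < 1e-12) return(rep(mean_t, n))
  fallback <- NULL
  for (i in seq_len(max_retries)) {
    z <- stats::rnorm(n)
    y <- fit_cubic_sample(z, skew_t, kurt_t)
    if (is.null(y)) next
    out <- mean_t + sd_raw * as.numeric(y)
    attr(out, "coef") <- attr(y, "coef")
    if (!require_positive || min(out) > 0) return(out)
    if (is.null(fallback)) fallback <- out
  }
  if (!is.null(fallback)) return(fallback)
  stop(sprintf(paste0("moment solver failed for targets (mean=%.4g, SD=%.4g, ",
                      "skew=%.4g, kurt=%.4g) after %d retries"),
               mean_t, sd_t, skew_t, kurt_t, max_retries))
}

# Filled ellipse mask; radii in pixels, center in (row, col).
make_ellipse_mask <- function(shape, center, radii) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cl <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((cl - center[2]) / radii[2])^2 <= 1
}

# Second-reader mask: radii scaled and center shifted by up to `jitter`
# (fraction of the radii). Guaranteed to differ from the reference mask in
# at least one pixel when jitter > 0.
jitter_mask <- function(shape, center, radii, jitter) {
  if (jitter == 0) return(make_ellipse_mask(shape, center, radii))
  scale <- 1 + stats::runif(2, -jitter, jitter)
  shift <- stats::runif(2, -jitter, jitter) * radii
  m2 <- make_ellipse_mask(shape, center + shift, radii * scale)
  m1 <- make_ellipse_mask(shape, center, radii)
  if (identical(m1, m2)) # discrete grid swallowed the perturbation
    m2 <- make_ellipse_mask(shape, center, radii - c(1, 0))
  m2
}

#' Synthesize one ADC map and ROI mask from per-patient targets
#'
#' Realizes a single timepoint of a patient's target quadruple as pixel
#' data: an elliptical ROI whose interior is moment-matched noise, embedded
#' in a smooth positive background. Positivity is enforced by redrawing
#' noise that produces non-positive pixels; for heavy-tailed targets where
#' every draw crosses zero, the left tail is clipped and the exact mean/SD
#' restored (`n_clipped` pixels logged). A global affine `floor_shift` is
#' kept as a final guarantee and is 0 in practice.
#'
#' @param targets one row of [sample_feature_targets()] output (or any list
#'   with `<tp>_mean`, `<tp>_SD`, `<tp>_skewness`, `<tp>_kurtosis` fields).
#' @param timepoint `"pre"` or `"post"`.
#' @param roi_shape image dimensions.
#' @param seed integer seed.
#' @param radii,center optional ellipse geometry (pixels); defaults to a
#'   centered ellipse filling ~60% of the image.
#' @param reader2_jitter if > 0, also build a jittered second-reader mask.
#' @return list with `image` ([adc_map]), `mask`, `mask_reader2`
#'   ([roi_mask]s; reader 2 `NULL` unless requested) and `floor_shift`.
#' @export
synthesize_roi_image <- function(targets, timepoint = c("pre", "post"),
                                 roi_shape = c(64, 64), seed = 1L,
                                 radii = NULL, center = NULL,
                                 reader2_jitter = 0) {
  timepoint <- match.arg(timepoint)
  set.seed(seed)
  if (is.null(center)) center <- (roi_shape + 1) / 2
  if (is.null(radii)) radii <- roi_shape * 0.3
  g <- function(f) targets[[paste0(timepoint, "_", f)]]
  mask <- make_ellipse_mask(roi_shape, center, radii)
  n_fg <- sum(mask)
  if (n_fg < 16) stop("ROI ellipse below pixel floor")
  vals <- synthesize_values(n_fg, g("mean"), g("SD"),
                            g("skewness"), g("kurtosis"),
                            require_positive = TRUE)
  # tumor margin halo: pixels just outside the consensus outline follow the
  # same intensity distribution as the ROI (partial-volume tumor edge), so a
  # plausibly misplaced reader boundary samples tumor-like values rather
  # than clean background
  halo <- make_ellipse_mask(roi_shape, center, radii * 1.25) & !mask
  n_halo <- sum(halo)
  halo_vals <- if (n_halo > 3 && !is.null(attr(vals, "coef"))) {
    cf <- attr(vals, "coef")
    z <- stats::rnorm(n_halo)
    y <- z + cf[1] * z^2 + cf[2] * z^3
    y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
    pmax(g("mean") + g("SD") / 100 * y, 1e-4)
  } else rep(g("mean"), n_halo)
  # positive background: non-tumor tissue sits near 1.4x10^-3 mm^2/s
  px <- matrix(1.4 + stats::rnorm(prod(roi_shape), 0, 0.05),
               roi_shape[1], roi_shape[2])
  # rare heavy-tailed targets can defeat positivity rejection: clip the
  # offending left tail and restore the exact mean/SD by an affine step
  # (slightly biasing skew/kurtosis for those patients, which is logged)
  n_clipped <- 0L
  if (min(vals) <= 0) {
    sd_raw <- g("SD") / 100
    for (it in 1:6) {
      n_clipped <- n_clipped + sum(vals <= 1e-4)
      vals <- pmax(vals, 1e-4)
      vals <- g("mean") + sd_raw * (vals - mean(vals)) /
        sqrt(mean((vals - mean(vals))^2))
      if (min(vals) > 0) break
    }
  }
  tpx <- t(px); tmask <- t(mask)
  tpx[t(halo)] <- halo_vals
  tpx[tmask] <- vals              # row-major fill to match masked_pixels()
  px <- t(tpx)
  floor_shift <- 0
  if (min(px) <= 0) {
    floor_shift <- -min(px) + 1e-6
    px <- px + floor_shift
  }
  mask2 <- NULL
  if (reader2_jitter > 0)
    mask2 <- roi_mask(jitter_mask(roi_shape, center, radii, reader2_jitter),
                      reader = "reader2")
  pid <- if (!is.null(targets$patient_id)) targets$patient_id else NA_character_
  list(image = adc_map(px, patient_id = pid, timepoint = timepoint),
       mask = roi_mask(mask, reader = "reader1"),
       mask_reader2 = mask2,
       floor_shift = floor_shift, n_clipped = n_clipped)
}

#' Generate a complete synthetic cohort
#'
#' End-to-end cohort realization: per-patient feature targets, pre/post ADC
#' maps with reader-1 and jittered reader-2 masks, clinical covariates, and
#' a manifest table. Fully reproducible from (config, seed).
#'
#' @param config a [cohort_config].
#' @param cohort_name label stored on every patient (`"primary"`,
#'   `"internal_validation"`, `"external_validation"`, ...).
#' @param intensity_scale global multiplicative perturbation applied to all
#'   images (e.g. 1.1 to emulate a different scanner); 1 means none.
#' @return list of class `adc_cohort`: `patients` (each with `patient_id`,
#'   `group`, `cohort`, `covariates`, and `pre`/`post` slots holding
#'   `image`, `mask`, `mask_reader2`), `targets`, `manifest`, `config`.
#' @export
generate_cohort <- function(config, cohort_name = "primary",
                            intensity_scale = 1) {
  stopifnot(inherits(config, "cohort_config"))
  targets <- sample_feature_targets(config)   # seeds RNG with config$seed
  shape <- config$roi_shape
  n <- nrow(targets)
  # per-patient geometry and covariates drawn after targets, same stream
  set.seed(config$seed + 1L)
  radii_a <- stats::runif(n, 0.26, 0.36) * shape[1]
  radii_b <- stats::runif(n, 0.22, 0.32) * shape[2]
  centers <- cbind(shape[1] / 2 + stats::runif(n, -2, 2),
                   shape[2] / 2 + stats::runif(n, -2, 2))
  covars <- simulate_covariates(targets$group)
  img_seeds <- sample.int(.Machine$integer.max - 1L, 2 * n)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    tgt <- targets[i, ]
    tps <- list()
    for (j in 1:2) {
      tp <- c("pre", "post")[j]
      r <- synthesize_roi_image(
        tgt, timepoint = tp, roi_shape = shape, seed = img_seeds[2 * (i - 1) + j],
        radii = c(radii_a[i], radii_b[i]), center = centers[i, ],
        reader2_jitter = config$reader2_mask_jitter)
      if (is.null(r$mask_reader2))
        r$mask_reader2 <- roi_mask(r$mask$mask, reader = "reader2")
      if (intensity_scale != 1) {
        px <- r$image$pixels * intensity_scale
        r$image <- adc_map(px, spacing = r$image$spacing,
                           patient_id = r$image$patient_id, timepoint = tp)
      }
      tps[[tp]] <- r
    }
    patients[[i]] <- list(
      patient_id = targets$patient_id[i],
      group = targets$group[i],
      cohort = cohort_name,
      covariates = covars[i, ],
      pre = tps$pre, post = tps$post
    )
  }
  manifest <- data.frame(
    patient_id = targets$patient_id,
    cohort = cohort_name,
    group = targets$group,
    pre_image = NA_character_, pre_mask = NA_character_,
    pre_mask_reader2 = NA_character_,
    post_image = NA_character_, post_mask = NA_character_,
    post_mask_reader2 = NA_character_,
    age = covars$age, sex = covars$sex, cT = covars$cT, cN = covars$cN,
    stringsAsFactors = FALSE
  )
  structure(list(patients = patients, targets = targets, manifest = manifest,
                 config = config, cohort_name = cohort_name),
            class = "adc_cohort")
}

# Clinical covariates drawn from group-conditional distributions typical of
# an NCT rectal-cancer cohort: age ~ N(49, 14) / N(54, 12), ~70-78% male,
# mostly cT3, node-positive majority.
simulate_covariates <- function(group) {
  n <- length(group)
  nr <- group == "nonresponse"
  age <- round(ifelse(nr, stats::rnorm(n, 49.4, 14.2),
                      stats::rnorm(n, 54.2, 12.0)))
  age <- pmin(pmax(age, 18), 90)
  sex <- ifelse(stats::runif(n) < ifelse(nr, 0.778, 0.696), "M", "F")
  rcat <- function(p_nr, p_r, levels) {
    idx <- ifelse(nr,
                  findInterval(stats::runif(n), cumsum(p_nr)) + 1,
                  findInterval(stats::runif(n), cumsum(p_r)) + 1)
    levels[idx]
  }
  cT <- rcat(c(0.083, 0.806, 0.111), c(0.076, 0.722, 0.202),
             c("T2", "T3", "T4"))
  cN <- rcat(c(0.111, 0.500, 0.389), c(0.272, 0.367, 0.361),
             c("N0", "N1", "N2"))
  data.frame(age = age, sex = sex, cT = cT, cN = cN,
             stringsAsFactors = FALSE)
}

#' Write a cohort to disk
#'
#' Emits per-patient image and mask files (NIfTI or 16-bit PNG + JSON
#' sidecar) plus the manifest CSV with resolved paths. On any write failure
#' the partially written output directory is removed.
#'
#' @param cohort an `adc_cohort`.
#' @param dir output directory (created).
#' @param format `"nifti"` or `"png"`.
#' @return The manifest `data.frame` with populated path columns
#'   (invisibly); the manifest CSV lands at `dir/manifest.csv`.
#' @export
write_cohort <- function(cohort, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".png"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  ok <- FALSE
  on.exit(if (!ok) unlink(dir, recursive = TRUE))
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    for (tp in c("pre", "post")) {
      base <- file.path(dir, paste0(p$patient_id, "_", tp))
      write_adc_image(p[[tp]]$image, paste0(base, ext))
      write_roi_mask(p[[tp]]$mask, paste0(base, "_mask", ext))
      write_roi_mask(p[[tp]]$mask_reader2, paste0(base, "_mask_r2", ext))
      manifest[i, paste0(tp, "_image")] <- paste0(base, ext)
      manifest[i, paste0(tp, "_mask")] <- paste0(base, "_mask", ext)
      manifest[i, paste0(tp, "_mask_reader2")] <- paste0(base, "_mask_r2", ext)
    }
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  ok <- TRUE
  invisible(manifest)
}

#' Simulate binary subjective reader calls
#'
#' Each true non-responder is called positive with probability `sens`; each
#' responder with probability `1 - spec`, independently.
#'
#' @param labels factor or character vector with levels
#'   response/nonresponse (nonresponse is the positive class).
#' @param sens,spec reader operating point, both in \[0, 1\].
#' @param seed integer seed.
#' @return integer vector of 0/1 calls.
#' @export
simulate_reader_calls <- function(labels, sens, spec, seed = 1L) {
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1)
    stop("sens and spec must lie in [0, 1]")
  set.seed(seed)
  pos <- labels == "nonresponse"
  u <- stats::runif(length(labels))
  as.integer(ifelse(pos, u < sens, u < 1 - spec))
}
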