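#' Randomly split one-center cases into primary and internal-validation
#' cohorts
#'
#' Seeded simple random split at the configured fraction (default 0.8,
#' matching the conventional ~4:1 development/validation split). Optional
#' stratification by response label keeps group prevalence equal across the
#' two cohorts.
#'
#' @param ids case identifiers.
#' @param fraction fraction assigned to the primary cohort, in (0, 1).
#' @param seed integer seed.
#' @param labels optional labels for stratified splitting.
#' @return character vector (same order as `ids`) of `"primary"` /
#'   `"internal_validation"`.
#' @export
split_cohorts <- function(ids, fraction = 0.8, seed = 1L, labels = NULL) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly inside (0, 1)")
  n <- length(ids)
  set.seed(seed)
  assign <- rep("internal_validation", n)
  if (is.null(labels)) {
    n_primary <- round(fraction * n)
    assign[sample.int(n, n_primary)] <- "primary"
  } else {
    for (g in unique(labels)) {
      idx <- which(labels == g)
      take <- round(fraction * length(idx))
      assign[sample(idx, take)] <- "primary"
    }
  }
  assign
}

#' Cohort demographic summary
#'
#' Counts, percentages and mean +/- SD summaries by response group, in the
#' shape of a clinical baseline-characteristics table, with the
#' between-group test from the evaluation rules attached per covariate.
#'
#' @param manifest cohort manifest `data.frame` with `group` plus optional
#'   `age`, `sex`, `cT`, `cN` columns.
#' @return list: `n`, `n_nonresponse`, `n_response`,
#'   `nonresponse_percent`, and a `covariates` table (variable, summary per
#'   group, test, p).
#' @export
summarize_cohort <- function(manifest) {
  stopifnot("group" %in% names(manifest))
  n <- nrow(manifest)
  n_nr <- sum(manifest$group == "nonresponse")
  rows <- list()
  for (v in intersect(c("age", "sex", "cT", "cN"), names(manifest))) {
    col <- manifest[[v]]
    if (all(is.na(col))) {
      warning("covariate '", v, "' is empty; omitted from summary")
      next
    }
    if (is.numeric(col)) {
      s <- function(g) sprintf("%.2f +/- %.2f",
                               mean(col[manifest$group == g]),
                               stats::sd(col[manifest$group == g]))
      tst <- tryCatch(compare_groups_numeric(col, manifest$group),
                      error = function(e) list(test = NA, p_value = NA))
      rows[[v]] <- data.frame(variable = v,
                              nonresponse = s("nonresponse"),
                              response = s("response"),
                              test = tst$test, p_value = tst$p_value,
                              stringsAsFactors = FALSE)
    } else {
      tab <- table(manifest$group, col)
      tst <- tryCatch(compare_groups_categorical(tab),
                      error = function(e) list(test = NA, p_value = NA))
      pct <- function(g) paste(sprintf("%s %d (%.1f%%)", colnames(tab),
                                       tab[g, ], 100 * tab[g, ] / sum(tab[g, ])),
                               collapse = "; ")
      rows[[v]] <- data.frame(variable = v,
                              nonresponse = pct("nonresponse"),
                              response = pct("response"),
                              test = tst$test, p_value = tst$p_value,
                              stringsAsFactors = FALSE)
    }
  }
  list(n = n, n_nonresponse = n_nr, n_response = n - n_nr,
       nonresponse_percent = 100 * n_nr / n,
       covariates = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Run the full texture-analysis study pipeline
#'
#' End-to-end execution on synthetic cohorts: generate a single-center
#' case pool and split it into primary and internal-validation cohorts,
#' generate an external cohort under a scanner intensity perturbation,
#' extract features, filter by inter-reader ICC, screen ADC candidates and
#' fit the forward-LR logistic ADC model, rank features by Gini importance
#' and fit the random-forest texture (TA) model, simulate two subjective
#' readers on the primary cohort, and evaluate everything with
#' ROC/DeLong/kappa. Only primary-cohort labels are used for feature
#' selection and model fitting.
#'
#' @param config a [cohort_config] describing the single-center pool
#'   (primary + internal validation together).
#' @param n_external_nonresponse,n_external_response external cohort group
#'   sizes (its prevalence deliberately differs from the development
#'   center).
#' @param split_fraction fraction of the center-A pool assigned to the
#'   primary cohort.
#' @param external_intensity_scale multiplicative intensity perturbation of
#'   the external-center images.
#' @param icc_threshold reproducibility cutoff.
#' @param k_select number of Gini-selected texture features.
#' @param n_trees forest size.
#' @param seed master seed for every stage.
#' @param out_dir if non-`NULL`, write `report.json` plus feature/ICC CSV
#'   tables there.
#' @return list of class `ta_report`; see the `evaluation` element for
#'   AUCs, DeLong comparisons and kappa.
#' @export
run_pipeline <- function(config = cohort_config(n_nonresponse = 45,
                                                n_response = 198),
                         n_external_nonresponse = 33,
                         n_external_response = 23,
                         split_fraction = 0.8,
                         external_intensity_scale = 1.1,
                         icc_threshold = 0.75,
                         k_select = 5, n_trees = 500,
                         seed = 1L, out_dir = NULL) {
  seed <- as.integer(seed)
  # --- simulate: one-center pool + external center -----------------------
  pool_cfg <- config
  pool_cfg$seed <- seed
  pool <- generate_cohort(pool_cfg, cohort_name = "centerA")
  ext_cfg <- cohort_config(
    n_nonresponse = n_external_nonresponse,
    n_response = n_external_response,
    feature_targets = config$feature_targets,
    rho = config$correlation,
    roi_shape = config$roi_shape,
    reader2_mask_jitter = config$reader2_mask_jitter,
    reader_sens = config$reader_sens, reader_spec = config$reader_spec,
    seed = seed + 1000L)
  external <- generate_cohort(ext_cfg, cohort_name = "external_validation",
                              intensity_scale = external_intensity_scale)
  # --- split center A ----------------------------------------------------
  assign <- split_cohorts(vapply(pool$patients, `[[`, character(1),
                                 "patient_id"),
                          fraction = split_fraction, seed = seed + 2000L)
  for (i in seq_along(pool$patients)) {
    pool$patients[[i]]$cohort <- assign[i]
  }
  pool$manifest$cohort <- assign
  # --- extract -----------------------------------------------------------
  feats_pool_r1 <- extract_features(pool, reader = "reader1")
  feats_pool_r2 <- extract_features(pool, reader = "reader2")
  feats_ext <- extract_features(external, reader = "reader1")
  primary <- feats_pool_r1[feats_pool_r1$cohort == "primary", ]
  internal <- feats_pool_r1[feats_pool_r1$cohort == "internal_validation", ]
  primary_r2 <- feats_pool_r2[feats_pool_r2$cohort == "primary", ]
  # --- reproducibility filter (primary cohort only) ----------------------
  icc <- icc_report(primary, primary_r2, threshold = icc_threshold)
  retained <- filter_features(icc, threshold = icc_threshold)
  if (length(retained) == 0)
    stop("stage icc: no feature passed the reproducibility threshold")
  # --- group comparisons (primary) ---------------------------------------
  comparisons <- do.call(rbind, lapply(all_feature_names(), function(f) {
    tst <- compare_groups_numeric(primary[[f]], primary$label)
    data.frame(feature = f, test = tst$test, p_value = tst$p_value,
               stringsAsFactors = FALSE)
  }))
  # --- ADC model ---------------------------------------------------------
  adc_candidates <- select_significant_adc_candidates(primary)
  # with no significant candidate, forward selection at the usual threshold
  # almost always yields the intercept-only model (constant risk, AUC 0.5)
  adc_model <- forward_lr_logistic(
    primary,
    if (length(adc_candidates)) adc_candidates
    else c("pre_ADC", "post_ADC", "ADC_change"))
  # --- TA model ----------------------------------------------------------
  ranked <- rank_features_gini(primary, features = retained,
                               n_trees = n_trees, k = k_select,
                               seed = seed + 3000L)
  ta_model <- fit_ta_model(primary, features = ranked$selected,
                           n_trees = n_trees, seed = seed + 4000L)
  # --- subjective readers (primary cohort) -------------------------------
  reader_calls <- lapply(seq_along(config$reader_sens), function(r)
    simulate_reader_calls(primary$label, config$reader_sens[r],
                          config$reader_spec[r], seed = seed + 5000L + r))
  # --- evaluation --------------------------------------------------------
  eval_cohort <- function(tab) {
    ta_scores <- predict(ta_model, tab)
    adc_scores <- predict(adc_model, tab)
    list(ta = roc_auc(ta_scores, tab$label),
         adc = roc_auc(adc_scores, tab$label),
         ta_scores = ta_scores, adc_scores = adc_scores)
  }
  ev_primary <- eval_cohort(primary)
  ev_internal <- eval_cohort(internal)
  ev_external <- eval_cohort(feats_ext)
  reader_rocs <- lapply(reader_calls, binary_rater_roc, labels = primary$label)
  delong <- list(
    ta_vs_adc = delong_paired_test(ev_primary$ta_scores,
                                   ev_primary$adc_scores, primary$label),
    ta_vs_reader1 = delong_paired_test(ev_primary$ta_scores,
                                       as.numeric(reader_calls[[1]]),
                                       primary$label),
    ta_vs_reader2 = delong_paired_test(ev_primary$ta_scores,
                                       as.numeric(reader_calls[[2]]),
                                       primary$label))
  kappa <- cohens_kappa(reader_calls[[1]], reader_calls[[2]])
  report <- structure(list(
    seed = seed,
    settings = list(split_fraction = split_fraction,
                    external_intensity_scale = external_intensity_scale,
                    icc_threshold = icc_threshold, k_select = k_select,
                    n_trees = n_trees,
                    reader2_mask_jitter = config$reader2_mask_jitter),
    cohort_summary = list(
      primary = summarize_cohort(pool$manifest[assign == "primary", ]),
      internal_validation =
        summarize_cohort(pool$manifest[assign == "internal_validation", ]),
      external_validation = summarize_cohort(external$manifest)),
    icc = icc, retained_features = retained,
    group_comparisons = comparisons,
    adc_candidates = adc_candidates,
    adc_model = adc_model,
    ranked_features = ranked,
    ta_model = ta_model,
    evaluation = list(
      primary = list(ta = ev_primary$ta, adc = ev_primary$adc,
                     reader1 = reader_rocs[[1]], reader2 = reader_rocs[[2]]),
      internal_validation = list(ta = ev_internal$ta, adc = ev_internal$adc),
      external_validation = list(ta = ev_external$ta, adc = ev_external$adc),
      delong = delong, kappa = kappa),
    features = list(primary = primary, internal = internal,
                    external = feats_ext)
  ), class = "ta_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.ta_report <- function(x, ...) {
  ev <- x$evaluation
  cat("ADC texture-analysis pipeline report (seed", x$seed, ")\n")
  cat(sprintf("  primary:  TA AUC %.3f | ADC AUC %.3f | readers %.3f / %.3f\n",
              ev$primary$ta$auc, ev$primary$adc$auc,
              ev$primary$reader1$auc, ev$primary$reader2$auc))
  cat(sprintf("  internal: TA AUC %.3f | external: TA AUC %.3f\n",
              ev$internal_validation$ta$auc, ev$external_validation$ta$auc))
  cat(sprintf("  DeLong TA vs ADC p = %.3g; reader kappa = %.3f\n",
              ev$delong$ta_vs_adc$p_value, ev$kappa$kappa))
  cat("  TA features:", paste(x$ranked_features$selected, collapse = ", "),
      "\n")
  invisible(x)
}

#' Write pipeline report artifacts
#'
#' Emits `report.json` (AUCs with CIs, DeLong p-values, kappa, retained
#' features, settings and seed) plus CSV tables for features, ICC and group
#' comparisons.
#'
#' @param report a `ta_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- report$evaluation
  roc_json <- function(r)
    list(auc = r$auc, ci = r$ci,
         sensitivity = r$youden$sensitivity,
         specificity = r$youden$specificity)
  js <- list(
    seed = report$seed,
    settings = report$settings,
    retained_features = report$retained_features,
    selected_features = report$ranked_features$selected,
    adc_model_terms = report$adc_model$entered,
    evaluation = list(
      primary = lapply(ev$primary, roc_json),
      internal_validation = lapply(ev$internal_validation, roc_json),
      external_validation = lapply(ev$external_validation, roc_json),
      delong_p = lapply(ev$delong, `[[`, "p_value"),
      kappa = list(kappa = ev$kappa$kappa, ci = ev$kappa$ci)))
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$features$primary,
                   file.path(dir, "features_primary.csv"), row.names = FALSE)
  utils::write.csv(report$icc, file.path(dir, "icc.csv"), row.names = FALSE)
  utils::write.csv(report$group_comparisons,
                   file.path(dir, "group_comparisons.csv"), row.names = FALSE)
  invisible(dir)
}
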