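# Shared fixtures: tiny maps/masks built in code, and a small fast cohort
# configuration for pipeline-level tests.

map_2x2 <- function() {
  adctex::adc_map(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE),
                  patient_id = "T01", timepoint = "pre")
}

full_mask <- function(shape = c(2, 2), floor = 1) {
  adctex::roi_mask(matrix(TRUE, shape[1], shape[2]), pixel_floor = floor)
}

# small cohort: 8 + 12 patients, 48x48 images; fast enough for unit tests
small_config <- function(seed = 42L, jitter = 0.05) {
  adctex::cohort_config(n_nonresponse = 8, n_response = 12,
                        roi_shape = c(48, 48),
                        reader2_mask_jitter = jitter, seed = seed)
}

# rank-based Mann-Whitney AUC, independent of the ROC implementation
u_statistic_auc <- function(scores, labels) {
  pos <- scores[labels == "nonresponse"]
  neg <- scores[labels == "response"]
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}
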