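test_that("zero-dispersion targets collapse to the group means", {
  ft <- default_feature_targets()
  ft$nonresponse_sd[] <- 0
  ft$response_sd[] <- 0
  cfg <- cohort_config(n_nonresponse = 3, n_response = 3,
                       feature_targets = ft, seed = 9)
  tg <- sample_feature_targets(cfg)
  nr <- tg[tg$group == "nonresponse", ]
  expect_true(all(abs(nr$pre_mean - 0.962) < 1e-12))
  expect_true(all(abs(nr$pre_SD - 12.081) < 1e-12))
  expect_true(all(abs(nr$post_mean - (0.962 - 0.056)) < 1e-12))
  # constant-image limit
  v <- synthesize_values(100, 1.0, 0, 0, 0)
  expect_equal(v, rep(1.0, 100))
})

test_that("target sampling is deterministic and post = pre + change", {
  cfg <- small_config(seed = 5)
  t1 <- sample_feature_targets(cfg)
  t2 <- sample_feature_targets(cfg)
  expect_identical(t1, t2)
  expect_true(all(t1$pre_SD > 0) && all(t1$post_SD > 0))
  # feasibility: every (skew, kurt) pair lies in the attainable region
  for (tp in c("pre", "post")) {
    s <- t1[[paste0(tp, "_skewness")]]
    k <- t1[[paste0(tp, "_kurtosis")]]
    expect_true(all(k >= 1.6410373 * s^2 - 1.2264489 + 0.1 - 1e-8))
    expect_true(all(k >= s^2 - 2))
  }
})

test_that("group target means recover configured means at large n", {
  cfg <- cohort_config(n_nonresponse = 1000, n_response = 2, seed = 42)
  tg <- sample_feature_targets(cfg)
  nr <- tg[tg$group == "nonresponse", ]
  # location/scale features are untouched by feasibility projection
  expect_lt(abs(mean(nr$post_mean) - 0.906), 3 * 0.240 / sqrt(1000))
  expect_lt(abs(mean(nr$pre_mean) - 0.962), 3 * 0.229 / sqrt(1000))
  expect_lt(abs(mean(nr$pre_SD) - 12.081), 3 * 2.208 / sqrt(1000))
  expect_lt(abs(sd(nr$pre_mean) - 0.229), 3 * 0.229 / sqrt(2 * 1000))
})

test_that("feasibility projection is a nearest-point projection", {
  floor_fn <- function(s) 1.6410373 * s^2 - 1.2264489 + 0.1
  cases <- list(c(0, -3), c(2, 0), c(-1.5, -2), c(0.5, -1.4), c(3, 5))
  for (cs in cases) {
    pr <- project_feasible_moments(cs[1], cs[2])
    if (!pr$moved) {
      expect_gte(cs[2], floor_fn(cs[1]))
      next
    }
    d_impl <- sqrt((pr$skew - cs[1])^2 + (pr$kurt - cs[2])^2)
    # grid-search oracle over the boundary curve
    sg <- seq(cs[1] - 6, cs[1] + 6, length.out = 20001)
    d_grid <- min(sqrt((sg - cs[1])^2 + (floor_fn(sg) - cs[2])^2))
    expect_lte(d_impl, d_grid + 1e-4)
    expect_equal(pr$kurt, floor_fn(pr$skew), tolerance = 1e-8)
  }
})

test_that("synthesized pixels round-trip their target moments", {
  set.seed(1)
  # fixed clinically plausible quadruple plus random feasible targets
  cases <- rbind(
    c(0.906, 12.8, 0.405, 1.133),
    c(1.0, 12.0, 0, 0),
    cbind(runif(25, 0.5, 1.5), runif(25, 8, 20),
          sk <- runif(25, -1.5, 2.5),
          1.6410373 * sk^2 - 1.2264489 + 0.1 + runif(25, 0.05, 4)))
  for (i in seq_len(nrow(cases))) {
    tg <- cases[i, ]
    v <- synthesize_values(3000, tg[1], tg[2], tg[3], tg[4])
    s <- first_order_stats(v)
    expect_lt(abs(s$mean - tg[1]) / tg[1], 1e-2)
    expect_lt(abs(s$sd - tg[2]) / tg[2], 1e-2)
    expect_lt(abs(s$skewness - tg[3]), 0.1)
    expect_lt(abs(s$kurtosis - tg[4]), 0.1)
  }
})

test_that("gaussian targets give near-zero skewness on a full ROI", {
  tgt <- list(pre_mean = 1.0, pre_SD = 12, pre_skewness = 0,
              pre_kurtosis = 0, patient_id = "G1")
  r <- synthesize_roi_image(tgt, "pre", roi_shape = c(64, 64), seed = 2)
  s <- first_order_stats(masked_pixels(r$image, r$mask))
  expect_lt(abs(s$skewness), 0.1)
  expect_lt(abs(s$kurtosis), 0.1)
  expect_equal(s$mean, 1.0, tolerance = 1e-6)
  expect_equal(r$floor_shift, 0)
  expect_true(all(r$image$pixels > 0))
})

test_that("cohort generation is reproducible and sized correctly", {
  cfg <- cohort_config(n_nonresponse = 36, n_response = 158, seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$manifest), 194)
  expect_equal(sum(co$manifest$group == "nonresponse"), 36)
  co2 <- generate_cohort(cfg)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$patients[[5]]$post$image$pixels,
                   co2$patients[[5]]$post$image$pixels)
})

test_that("reader-2 masks are identical without jitter, perturbed with it", {
  co0 <- generate_cohort(small_config(seed = 8, jitter = 0))
  for (p in co0$patients) {
    expect_identical(p$pre$mask$mask, p$pre$mask_reader2$mask)
    expect_identical(p$post$mask$mask, p$post$mask_reader2$mask)
  }
  f1 <- extract_features(co0, "reader1")
  f2 <- extract_features(co0, "reader2")
  rep0 <- icc_report(f1, f2)
  expect_true(all(abs(rep0$icc - 1) < 1e-9))
  expect_true(all(rep0$keep))

  coj <- generate_cohort(small_config(seed = 8, jitter = 0.08))
  for (p in coj$patients) for (tp in c("pre", "post")) {
    m1 <- p[[tp]]$mask$mask
    m2 <- p[[tp]]$mask_reader2$mask
    expect_gte(sum(m1 != m2), 1)
    expect_gte(sum(m1 & m2) / sum(m1), 0.5)
  }
})

test_that("cohort writing emits readable images and a manifest", {
  co <- generate_cohort(cohort_config(n_nonresponse = 2, n_response = 2,
                                      roi_shape = c(48, 48), seed = 4))
  dir <- tempfile("cohort")
  man <- write_cohort(co, dir, format = "png")
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), 4)
  m <- read_adc_image(man$pre_image[1], patient_id = man$patient_id[1])
  expect_equal(m$pixels, co$patients[[1]]$pre$image$pixels,
               tolerance = 1e-4)
  msk <- read_roi_mask(man$pre_mask[1])
  expect_identical(msk$mask, co$patients[[1]]$pre$mask$mask)
  unlink(dir, recursive = TRUE)
})

test_that("simulated reader calls hit their operating point", {
  labels <- factor(rep(c("nonresponse", "response"), c(36, 158)))
  expect_identical(simulate_reader_calls(labels, 1, 1, seed = 1),
                   as.integer(labels == "nonresponse"))
  expect_identical(simulate_reader_calls(labels, 0, 1, seed = 1),
                   rep(0L, 194))
  expect_error(simulate_reader_calls(labels, 1.2, 0.5), "\\[0, 1\\]")
  # binomial expectation over replicates
  sens_hat <- vapply(1:2000, function(s) {
    calls <- simulate_reader_calls(labels, 0.278, 0.956, seed = s)
    mean(calls[labels == "nonresponse"])
  }, numeric(1))
  expect_lt(abs(mean(sens_hat) - 0.278), 0.01)
})
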