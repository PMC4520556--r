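# Experiment drivers at reduced problem sizes; full study-condition runs live
# in test-acceptance.R.

test_that("linearity driver recovers the calibration slope on clean scenes", {
  res <- run_linearity("wheel", c(5, 15, 25, 40), seed = 2, duration = 10,
                       sigma0 = 1e-3, broadening_coeff = 0,
                       detector_noise_psd = 0)
  expect_equal(res$slope, 651 / 24, tolerance = 0.01)
  expect_gt(res$pearson_r, 0.9999)
  expect_equal(nrow(res$summary), 4)
})

test_that("linearity r degrades weakly with detector noise", {
  clean <- run_linearity("capillary", c(1, 5, 15, 40), seed = 3,
                         duration = 10, detector_noise_psd = 0)
  noisy <- run_linearity("capillary", c(1, 5, 15, 40), seed = 3,
                         duration = 10, detector_noise_psd = 1e-6)
  expect_gte(clean$pearson_r, noisy$pearson_r - 1e-4)
  expect_gt(clean$pearson_r, 0.999)
})

test_that("linearity driver validates its speed ranges", {
  expect_error(run_linearity("wheel", c(1, 10, 20, 30), seed = 1),
               "motor floor")
  expect_error(run_linearity("capillary", c(0.1, 1, 10, 40), seed = 1),
               "0.3-50")
  expect_error(run_linearity("wheel", c(5, 10), seed = 1), "at least 4")
})

test_that("baseline driver with no between-rat variance shows only estimator noise", {
  p <- cohort_params("artery", n_rats = 4, sd_between = 0, sd_session = 0,
                     sd_minute = 0)
  res <- run_baseline("artery", n_rats = 4, seed = 5, duration = 20,
                      params = p)
  expect_equal(res$mean, 651, tolerance = 0.02)
  expect_lt(res$sd, 15)
})

test_that("repeatability driver: zero within-rat variance drives all ICCs to 1", {
  p <- cohort_params("artery", n_rats = 5, sd_session = 0, sd_minute = 0,
                     sd_reposition = 0)
  res <- run_repeatability("artery", n_rats = 5, seed = 6,
                           session_duration = 10, include_interday = TRUE,
                           params = p)
  expect_true(all(res$table_rows$icc > 0.98))
  expect_true(all(res$table_rows$vc_mean < 2))
})

test_that("repeatability driver: independent redraw per session kills the ICC", {
  p <- cohort_params("artery", n_rats = 8, sd_between = 5, sd_session = 300,
                     sd_minute = 0)
  res <- run_repeatability("artery", n_rats = 8, seed = 8,
                           session_duration = 10, include_interday = FALSE,
                           params = p)
  expect_lt(res$table_rows$icc[res$table_rows$timescale == "inter-session"],
            0.35)
})

test_that("repeatability reports intra-session rows only when minutes exist", {
  p <- cohort_params("artery", n_rats = 4)
  short <- run_repeatability("artery", 4, seed = 2, session_duration = 10,
                             include_interday = FALSE, params = p)
  expect_equal(short$table_rows$timescale, "inter-session")
  long <- run_repeatability("artery", 4, seed = 2, session_duration = 120,
                            sessions = 2, include_interday = FALSE,
                            params = p)
  expect_setequal(long$table_rows$timescale,
                  c("intra-session", "inter-session"))
})

test_that("protocol driver with unit attenuation measures no change", {
  tl <- protocol_timeline(c("base", "sham"), c(30, 30), c(1, 1))
  res <- run_protocol("iop_clamp", "artery", n_rats = 4, seed = 4,
                      timeline = tl, guard = 5)
  expect_lt(abs(res$mean_change), 1.5)
})

test_that("protocol driver recovers a configured decrease at reduced scale", {
  tl <- protocol_timeline(c("base", "clamp"), c(30, 30), c(1, 0.31))
  res <- run_protocol("iop_clamp", "artery", n_rats = 5, seed = 10,
                      timeline = tl, guard = 5)
  expect_lt(abs(res$mean_change - 69), 2)
  expect_equal(res$wilcoxon$p, 0.0625) # n = 5, all decreases, exact
})

test_that("experiments are reproducible from (config, seed)", {
  a <- run_linearity("wheel", c(5, 15, 25, 40), seed = 12, duration = 5)
  b <- run_linearity("wheel", c(5, 15, 25, 40), seed = 12, duration = 5)
  expect_identical(a$summary, b$summary)
  expect_identical(a$pearson_r, b$pearson_r)
})

test_that("tidy and glance expose the experiment tables", {
  res <- run_linearity("wheel", c(5, 15, 25, 40), seed = 2, duration = 5)
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_named(g, c("scene_kind", "n_speeds", "pearson_r", "pearson_p",
                    "slope", "intercept", "vol_cv", "dc_cv"))
})
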