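test_that("acquisition config enforces the frame/rate relationship", {
  cfg <- default_cfg
  expect_equal(cfg$spectra_per_second, 14)
  expect_equal(cfg$df, 14)
  expect_equal(cfg$nyquist, 7168)
  expect_error(acquisition_config(sampling_rate = 14000, frame_length = 1024),
               "integer number of spectra")
  expect_error(acquisition_config(analysis_band = c(28, 8000)), "Nyquist")
})

test_that("derived child seeds are deterministic and distinct", {
  expect_identical(ldfsim:::derive_seed(1, 2, 3), ldfsim:::derive_seed(1, 2, 3))
  s <- c(ldfsim:::derive_seed(1, 1), ldfsim:::derive_seed(1, 2),
         ldfsim:::derive_seed(2, 1))
  expect_equal(length(unique(s)), 3)
  expect_true(all(s >= 0 & s < 2^31))
})

test_that("wheel line sits at k_cal * speed and capillary mean at k_cal * speed", {
  sc <- scene_wheel(10, k_cal = 27.1)
  expect_equal(sc$centre_freq, 271)
  ts <- target_spectrum(sc, default_cfg)
  expect_lt(abs(ts$frequency[which.max(ts$psd)] - 271), 15)
  # capillary: uniform speeds on [0, 2v] have mean v; band-limiting cuts
  # the [0, band_lo] slice, lifting the moment by ~band_lo / 2
  scc <- scene_capillary(20, k_cal = 27.1)
  tr <- scene_truth(scc, default_cfg)
  expect_lt(abs(tr$vel_true - (27.1 * 20 + 14)), 2)
})

test_that("scene truths agree with an independent quadrature oracle", {
  cfg <- default_cfg
  band <- cfg$analysis_band
  sc <- scene_wheel(15)
  oracle <- quadrature_moment(function(f) ldfsim:::scene_shape(sc, f), band)
  expect_lt(abs(scene_truth(sc, cfg)$vel_true - oracle), 0.1)
  sa <- scene_artery(651)
  oracle_a <- quadrature_moment(function(f) exp(-f / sa$tau), band)
  expect_lt(abs(oracle_a - 651), 0.2)
  expect_lt(abs(scene_truth(sa, cfg)$vel_true - 651), 0.2)
  so <- scene_onh(369)
  oracle_o <- quadrature_moment(function(f) ldfsim:::scene_shape(so, f), band)
  expect_lt(abs(oracle_o - 369), 1)
})

test_that("solve_spectrum_rate hits targets, is monotone, and rejects edges", {
  band <- c(28, 5012)
  tau <- solve_spectrum_rate(651, band)
  expect_lt(abs(ldfsim:::exp_band_moment(tau, band[1], band[2]) - 651), 0.05)
  # flat-spectrum limit: moment -> band midpoint as tau -> Inf
  expect_lt(abs(ldfsim:::exp_band_moment(1e9, band[1], band[2]) - mean(band)), 0.5)
  taus <- vapply(c(100, 300, 651, 1200, 2000), solve_spectrum_rate,
                 numeric(1), band = band)
  expect_true(all(diff(taus) > 0))
  expect_error(solve_spectrum_rate(28, band), "unattainable")
  expect_error(solve_spectrum_rate(2600, band), "unattainable")
})

test_that("target spectra carry total power modulation_depth * dc^2", {
  cfg <- default_cfg
  for (sc in list(scene_wheel(12), scene_capillary(10), scene_artery(500),
                  scene_onh(300))) {
    scale <- ldfsim:::scene_psd_scale(sc, cfg)
    f <- seq(0.5, cfg$nyquist, by = 0.5)
    total <- sum(scale * ldfsim:::scene_shape(sc, f)) * 0.5
    expect_equal(total, sc$modulation_depth * sc$dc_level^2,
                 tolerance = 0.02, info = sc$kind)
  }
})

test_that("scene constructors reject out-of-band and invalid targets", {
  expect_error(scene_wheel(300), "above the analysis band")
  expect_error(scene_capillary(250), "above the analysis band")
  expect_error(scene_artery(10), "unattainable")
  expect_error(scene_onh(20), "band lower edge")
  expect_error(scene_onh(40), "attainable minimum")
  clamped <- scene_onh(40, clamp = TRUE)
  expect_true(clamped$clamped)
})

test_that("re-solving a scene at an attenuated target scales its truth", {
  cfg <- default_cfg
  sa <- scene_artery(651)
  att <- ldfsim:::scene_with_target(sa, 0.31 * 651, cfg)
  expect_lt(abs(scene_truth(att, cfg)$vel_true - 0.31 * 651), 0.1)
  fl <- ldfsim:::scene_with_target(sa, 10, cfg)
  expect_equal(fl$modulation_depth, 0)
  expect_true(isTRUE(fl$floor))
})
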