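test_that("zero modulation and zero noise give a constant trace at dc_level", {
  sc <- scene_wheel(10, modulation_depth = 0, detector_noise_psd = 0)
  rec <- synthesize_record(sc, 1, seed = 4)
  expect_equal(rec$samples, rep(sc$dc_level, length(rec$samples)))
})

test_that("synthesis satisfies Parseval: AC variance matches target power plus noise", {
  cfg <- default_cfg
  for (sc in list(scene_artery(651), scene_wheel(10))) {
    rec <- synthesize_record(sc, 40, seed = 11, cfg)
    expected <- sc$modulation_depth * sc$dc_level^2 +
      sc$detector_noise_psd * cfg$sampling_rate / 2
    # the sinusoid-sum construction fixes the signal variance exactly; the
    # tolerance covers detector-noise sampling and PSD discretisation
    expect_equal(stats::var(rec$samples), expected,
                 tolerance = 0.01, info = sc$kind)
  }
})

test_that("records are bit-identical for equal seeds and differ across seeds", {
  sc <- scene_artery(651)
  r1 <- synthesize_record(sc, 2, seed = 123)
  r2 <- synthesize_record(sc, 2, seed = 123)
  r3 <- synthesize_record(sc, 2, seed = 124)
  expect_identical(r1$samples, r2$samples)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("synthesis leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(synthesize_record(scene_artery(651), 1, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("records shorter than one frame are rejected", {
  expect_error(synthesize_record(scene_artery(651), 0.01, seed = 1),
               "shorter than one analysis frame")
})

test_that("protocol records are piecewise with per-segment truth", {
  cfg <- default_cfg
  tl <- protocol_timeline(c("base", "clamp", "rec"), c(20, 20, 20),
                          c(1, 0.31, 1))
  rec <- apply_protocol(scene_artery(651), tl, seed = 3, cfg)
  sm <- rec$segment_map
  expect_equal(nrow(sm), 3)
  expect_lt(abs(sm$vel_true[1] - 651), 0.1)
  expect_lt(abs(sm$vel_true[2] - 0.31 * 651), 0.1)
  expect_equal(rec$duration, 60)
  expect_equal(length(rec$samples), 60 * cfg$sampling_rate)
})

test_that("a single unit-attenuation segment reproduces synthesize_record", {
  cfg <- default_cfg
  sc <- scene_artery(500)
  tl <- protocol_timeline("only", 5, 1)
  rec_p <- apply_protocol(sc, tl, seed = 8, cfg)
  rec_s <- synthesize_record(sc, 5, ldfsim:::derive_seed(8, 1), cfg)
  expect_identical(rec_p$samples, rec_s$samples)
})

test_that("full attenuation clamps to a flagged floor segment", {
  tl <- protocol_timeline(c("base", "arrest"), c(5, 5), c(1, 0))
  rec <- apply_protocol(scene_artery(651), tl, seed = 2)
  expect_true(rec$segment_map$clamped[2])
  expect_equal(rec$segment_map$vel_true[2], 0)
  seg2 <- rec$samples[(5 * 14336 + 1):(10 * 14336)]
  noise_power <- 1e-8 * 14336 / 2 # detector noise only, no Doppler power
  expect_equal(stats::var(seg2), noise_power, tolerance = 0.05)
})

test_that("default protocol timelines encode the observed perfusion drops", {
  iop <- timeline_iop_clamp("artery")
  expect_equal(iop$vel_attenuation, c(1, 0.31, 1))
  expect_equal(iop$duration, c(120, 240, 300))
  ha <- timeline_heart_arrest("onh")
  expect_equal(ha$vel_attenuation[2], 0.59)
  expect_equal(ha$vol_attenuation[2], 0.59)
  expect_equal(timeline_heart_arrest("artery")$vel_attenuation[2], 0.19)
  expect_equal(timeline_iop_clamp("onh")$vel_attenuation[2], 0.955)
})
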