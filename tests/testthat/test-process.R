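test_that("framing yields 14 frames per second and drops the remainder", {
  cfg <- default_cfg
  rec <- synthesize_record(scene_artery(651), 40, seed = 1, cfg)
  expect_equal(ncol(frame_signal(rec, cfg)), 560)
  expect_equal(ncol(frame_signal(rep(0.3, 1024), cfg)), 1)
  expect_equal(ncol(frame_signal(rep(0.3, 1535), cfg)), 1)
  expect_error(frame_signal(rep(0.3, 1000), cfg), "shorter than one")
})

test_that("constant frames give zero power and zero noise floor", {
  sp <- compute_spectrum(rep(0.42, 1024), default_cfg)
  expect_equal(sp$dc, 0.42)
  expect_equal(max(sp$power), 0)
  expect_equal(sp$noise_floor, 0)
})

test_that("spectrum normalisation satisfies Parseval on bin-centred tones", {
  cfg <- default_cfg
  for (k in c(10, 50, 200, 357)) {
    fr <- tone_frame(k, a = 0.05, d = 0.4)
    sp <- compute_spectrum(fr, cfg)
    expect_equal(sp$dc, 0.4, tolerance = 1e-12)
    # windowed Parseval: sum(power) * df recovers the window-corrected AC
    # variance; for a bin-centred tone (k >= 2) the identity is exact
    w <- ldfsim:::analysis_window(cfg)
    ac <- fr - mean(fr)
    expect_equal(sum(sp$power) * cfg$df, sum((w * ac)^2) / sum(w^2),
                 tolerance = 1e-6)
    # and total band power equals a^2 / 2
    expect_equal(sum(sp$power) * cfg$df, 0.05^2 / 2, tolerance = 1e-9)
  }
})

test_that("white-noise frames show a flat spectrum at sigma^2 / nyquist", {
  cfg <- default_cfg
  sigma <- 0.01
  withr::with_seed(12, {
    frames <- matrix(0.5 + stats::rnorm(1024 * 400, 0, sigma), nrow = 1024)
  })
  pg <- ldfsim:::periodograms(frames, cfg)
  mean_psd <- rowMeans(pg$power)
  expect_equal(mean(mean_psd), sigma^2 / cfg$nyquist, tolerance = 0.02)
  # flat: band means agree within Monte-Carlo error
  low <- mean(mean_psd[pg$freq < 2000])
  high <- mean(mean_psd[pg$freq > 5000])
  expect_equal(low, high, tolerance = 0.02)
})

test_that("velocity equals the frequency of a pure bin-centred tone", {
  cfg <- default_cfg
  for (k in c(50, 150, 357)) {
    sp <- compute_spectrum(tone_frame(k, a = 0.08), cfg)
    expect_lt(abs(as.numeric(compute_vel(sp, cfg)) - k * cfg$df), 7)
  }
})

test_that("velocity of flat and degenerate spectra follows the moment definition", {
  cfg <- default_cfg
  freq <- ldfsim:::bin_frequencies(cfg)
  flat <- structure(list(frequency = freq, power = rep(1e-6, length(freq)),
                         dc = 0.4, noise_floor = 0), class = "ldf_spectrum")
  expect_equal(as.numeric(compute_vel(flat, cfg)), 2520)
  one_bin <- flat
  one_bin$power <- ifelse(freq == 700, 1e-5, 0)
  expect_equal(as.numeric(compute_vel(one_bin, cfg)), 700)
  silent <- flat
  silent$power <- rep(0, length(freq))
  v <- compute_vel(silent, cfg)
  expect_equal(as.numeric(v), 0)
  expect_false(attr(v, "valid"))
})

test_that("volume is scale-invariant and linear in modulation depth", {
  cfg <- default_cfg
  fr <- tone_frame(100, a = 0.06, d = 0.45)
  sp1 <- compute_spectrum(fr, cfg)
  sp2 <- compute_spectrum(3.3 * fr, cfg)
  expect_equal(compute_vol(sp1, cfg), compute_vol(sp2, cfg),
               tolerance = 1e-12)
  # doubling modulation depth at fixed dc doubles the 40-s mean Vol
  v1 <- average_trace(process_record(
    synthesize_record(scene_artery(651, modulation_depth = 0.1), 20, 5, cfg),
    cfg), 20)$vol_mean
  v2 <- average_trace(process_record(
    synthesize_record(scene_artery(651, modulation_depth = 0.2), 20, 6, cfg),
    cfg), 20)$vol_mean
  expect_equal(v2 / v1, 2, tolerance = 0.05)
  bad <- compute_spectrum(fr, cfg)
  bad$dc <- -1
  expect_error(compute_vol(bad, cfg), "non-physical")
})

test_that("velocity does not depend on brightness (dc_level) at fixed modulation", {
  cfg <- default_cfg
  v <- vapply(c(0.1, 0.35, 1), function(dc) {
    rec <- synthesize_record(scene_artery(651, dc_level = dc,
                                          detector_noise_psd = 0), 10, 9, cfg)
    average_trace(process_record(rec, cfg), 10)$vel_mean
  }, numeric(1))
  expect_lt(max(abs(v - v[2])), 1.0)
})

test_that("quality flag separates Doppler signal from detector noise", {
  cfg <- default_cfg
  noise_only <- scene_artery(651, modulation_depth = 0)
  tr_n <- process_record(synthesize_record(noise_only, 20, 3, cfg), cfg)
  # under the null the QC-band mean fluctuates around the noise floor
  expect_gt(mean(!tr_n$quality_ok), 0.30)
  tr_a <- process_record(synthesize_record(scene_artery(651), 20, 3, cfg), cfg)
  expect_gt(mean(tr_a$quality_ok), 0.99)
})

test_that("a DC step trips the stability flag until the median adapts", {
  cfg <- default_cfg
  # wheel scene: its Doppler line carries no near-DC power, so frame DC is
  # quiet and the step is the only instability
  rec <- synthesize_record(scene_wheel(10), 30, 21, cfg)
  half <- floor(length(rec$samples) / 2)
  rec$samples[(half + 1):length(rec$samples)] <-
    rec$samples[(half + 1):length(rec$samples)] * 1.2
  tr <- process_record(rec, cfg)
  step_frame <- ceiling(half / cfg$frame_length) + 1
  expect_true(all(tr$dc_stable[1:(step_frame - 1)]))
  expect_false(any(tr$dc_stable[step_frame:(step_frame + 3)]))
  expect_true(all(tr$dc_stable[(step_frame + 120):nrow(tr)]))
})

test_that("assess_quality matches the per-frame flags of process_record", {
  cfg <- default_cfg
  rec <- synthesize_record(scene_artery(651), 2, 13, cfg)
  frames <- frame_signal(rec, cfg)
  tr <- process_record(rec, cfg)
  sp <- compute_spectrum(frames[, 5], cfg)
  q <- assess_quality(sp, tr$dc[1:5], cfg)
  expect_equal(unname(q["quality_ok"]), tr$quality_ok[5])
  expect_equal(unname(q["dc_stable"]), tr$dc_stable[5])
})

test_that("end-to-end wheel recovery is within 2% and traces are deterministic", {
  cfg <- default_cfg
  sc <- scene_wheel(10)
  rec <- synthesize_record(sc, 40, seed = 31, cfg)
  tr <- process_record(rec, cfg)
  expect_equal(nrow(tr), 560)
  avg <- average_trace(tr, 40)
  expect_equal(avg$vel_mean, rec$truth$vel_true,
               tolerance = 0.02)
  tr2 <- process_record(synthesize_record(sc, 40, seed = 31, cfg), cfg)
  expect_identical(tr$vel, tr2$vel)
})

test_that("average_trace tiles windows and marks empty windows missing", {
  cfg <- default_cfg
  rec <- synthesize_record(scene_artery(651), 300, seed = 2, cfg)
  tr <- process_record(rec, cfg)
  avg <- average_trace(tr, 60)
  expect_equal(nrow(avg), 5)
  expect_false(any(avg$missing))
  expect_error(average_trace(tr, 400), "exceeds the trace duration")
  # all-invalid trace: window marked missing
  tr_bad <- tr[1:14, ]
  tr_bad$quality_ok <- FALSE
  attr(tr_bad, "cfg") <- cfg
  avg_bad <- average_trace(tr_bad, 1)
  expect_true(all(avg_bad$missing))
})
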