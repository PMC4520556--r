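#' Synthesize a photodetector signal record for a scene
#'
#' Generates a stationary record whose one-sided AC power spectral density
#' equals the scene's target spectrum, by frequency-domain synthesis: each
#' record-resolution frequency bin receives a spectral amplitude proportional
#' to `sqrt(PSD * df)` and an independent uniform phase, Hermitian symmetry is
#' imposed, and an inverse FFT returns the time series. White detector noise
#' of one-sided PSD `detector_noise_psd` and the scene's DC level are added.
#' Identical `(scene, duration, seed, cfg)` give bit-identical records.
#'
#' @param scene An [ldf_scene].
#' @param duration Record duration in seconds; at least one frame.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param cfg An [acquisition_config()].
#' @return An object of class `ldf_record`: a list with `samples` (volts),
#'   `sampling_rate`, `duration`, `scene`, `seed`, `truth` (ground-truth
#'   `vel_true` Hz, `vol_true` a.u., `dc_true` volts from [scene_truth()])
#'   and `segment_map` (`NULL` for stationary records).
#' @examples
#' rec <- synthesize_record(scene_wheel(10), duration = 2, seed = 1)
#' length(rec$samples) # 2 * 14336
#' @export
synthesize_record <- function(scene, duration, seed,
                              cfg = acquisition_config()) {
  n <- round(duration * cfg$sampling_rate)
  if (n < cfg$frame_length) {
    stop("duration ", duration, " s is shorter than one analysis frame (",
         cfg$frame_length / cfg$sampling_rate, " s)", call. = FALSE)
  }
  samples <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    ac <- synth_ac(scene, n, cfg)
    noise_sd <- sqrt(scene$detector_noise_psd * cfg$sampling_rate / 2)
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    scene$dc_level + ac + noise
  })
  structure(
    list(
      samples = samples,
      sampling_rate = cfg$sampling_rate,
      duration = n / cfg$sampling_rate,
      scene = scene,
      seed = as.integer(seed),
      truth = scene_truth(scene, cfg),
      segment_map = NULL
    ),
    class = "ldf_record"
  )
}

# Zero-mean Gaussian-like AC component with one-sided PSD equal to the
# scene's target spectrum. Consumes the current RNG stream (phases only).
synth_ac <- function(scene, n, cfg) {
  if (scene$modulation_depth == 0) return(numeric(n))
  df_rec <- cfg$sampling_rate / n
  if (scene$kind == "wheel" && scene$line_sd < 3 * df_rec) {
    # line narrower than the record's frequency resolution: the limit is a
    # pure tone at the Doppler shift with all the AC power
    amp <- sqrt(2 * scene$modulation_depth) * scene$dc_level
    phase <- stats::runif(1, 0, 2 * pi)
    t <- (0:(n - 1)) / cfg$sampling_rate
    return(amp * cos(2 * pi * scene$centre_freq * t + phase))
  }
  k_max <- floor((n - 1) / 2) # positive-frequency bins, Nyquist excluded
  f <- seq_len(k_max) * df_rec
  psd <- scene_psd_scale(scene, cfg) * scene_shape(scene, f)
  amp <- sqrt(2 * psd * df_rec) # per-bin cosine amplitude: var = psd * df
  phases <- stats::runif(k_max, 0, 2 * pi)
  spec <- complex(length.out = n)
  spec[2:(k_max + 1)] <- complex(modulus = (n / 2) * amp, argument = phases)
  spec[n:(n - k_max + 1)] <- Conj(spec[2:(k_max + 1)])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' @export
print.ldf_record <- function(x, ...) {
  cat("<ldf_record>", format(x$duration), "s of",
      x$scene$kind, "scene at", x$sampling_rate, "Hz\n")
  cat(sprintf("  seed %d | truth: vel %.1f Hz, vol %.3f a.u., dc %.3f V\n",
              x$seed, x$truth$vel_true, x$truth$vol_true, x$truth$dc_true))
  if (!is.null(x$segment_map)) {
    cat("  piecewise-stationary,", nrow(x$segment_map), "segments\n")
  }
  invisible(x)
}

#' Protocol timelines
#'
#' A protocol timeline is a tibble of consecutive piecewise-stationary
#' segments, each with a duration and multiplicative attenuation factors on
#' the scene's target first moment (`vel_attenuation`) and on its modulation
#' depth (`vol_attenuation`).
#'
#' `timeline_iop_clamp()` is the acute intraocular-hypertension protocol:
#' 2 min at baseline IOP, 4 min with IOP clamped at 150 mmHg, 5 min of
#' recovery. The default clamp attenuations are the complements of the
#' observed mean velocity decreases: arteries fall by 69% (factor 0.31) while
#' the optic nerve head signal barely changes (factor 0.955).
#' `timeline_heart_arrest()` is 2 min of pre-arrest baseline followed by
#' 5 min after cardiac arrest; velocity falls by 81% in arteries (factor
#' 0.19) and 41% at the ONH (factor 0.59), and the moving-scatterer volume is
#' assumed to fall with it (`vol_attenuation` equal to the velocity factor).
#'
#' @param label,duration,vel_attenuation,vol_attenuation Segment fields;
#'   vectors of equal length for `protocol_timeline()`.
#' @param site `"artery"` or `"onh"`; selects the default attenuation.
#' @param baseline_min,clamp_min,recovery_min,arrest_min Segment durations in
#'   minutes.
#' @return A tibble of class `ldf_timeline` with columns `label`, `duration`
#'   (s), `vel_attenuation`, `vol_attenuation`.
#' @examples
#' timeline_iop_clamp("artery")
#' @export
protocol_timeline <- function(label, duration, vel_attenuation,
                              vol_attenuation = rep(1, length(label))) {
  stopifnot(length(label) == length(duration),
            length(label) == length(vel_attenuation),
            length(label) == length(vol_attenuation),
            all(duration > 0), all(vel_attenuation >= 0),
            all(vol_attenuation >= 0))
  tl <- tibble::tibble(label = as.character(label),
                       duration = as.numeric(duration),
                       vel_attenuation = as.numeric(vel_attenuation),
                       vol_attenuation = as.numeric(vol_attenuation))
  class(tl) <- c("ldf_timeline", class(tl))
  tl
}

#' @rdname protocol_timeline
#' @export
timeline_iop_clamp <- function(site = c("artery", "onh"),
                               baseline_min = 2, clamp_min = 4,
                               recovery_min = 5) {
  site <- match.arg(site)
  att <- switch(site, artery = 0.31, onh = 0.955)
  protocol_timeline(
    label = c("baseline", "iop_150mmHg", "recovery"),
    duration = 60 * c(baseline_min, clamp_min, recovery_min),
    vel_attenuation = c(1, att, 1)
  )
}

#' @rdname protocol_timeline
#' @export
timeline_heart_arrest <- function(site = c("artery", "onh"),
                                  baseline_min = 2, arrest_min = 5) {
  site <- match.arg(site)
  att <- switch(site, artery = 0.19, onh = 0.59)
  protocol_timeline(
    label = c("baseline", "heart_arrest"),
    duration = 60 * c(baseline_min, arrest_min),
    vel_attenuation = c(1, att),
    vol_attenuation = c(1, att)
  )
}

#' Apply a protocol timeline to a baseline scene
#'
#' Produces a piecewise-stationary record: within each timeline segment the
#' scene's target first moment is `vel_attenuation` times the baseline target
#' (the spectral rate is re-solved per segment) and the modulation depth is
#' `vol_attenuation` times the baseline value. Segment lengths are rounded to
#' whole analysis frames so segment boundaries never straddle a frame. If an
#' attenuated target falls below the analysis band's lower edge the segment
#' is clamped to a floor scene (detector noise and DC only) and flagged in
#' the segment map.
#'
#' @param baseline_scene An artery or ONH [ldf_scene] (scenes with a solvable
#'   target first moment).
#' @param timeline A [protocol_timeline()].
#' @param seed Integer root seed; each segment uses a derived child seed.
#' @param cfg An [acquisition_config()].
#' @return An `ldf_record` whose `segment_map` tibble gives, per segment,
#'   `label`, `t_start`/`t_end` (s), the attenuation factors, the segment
#'   ground truth (`vel_true`, `vol_true`) and a `clamped` flag.
#' @examples
#' rec <- apply_protocol(scene_artery(651), timeline_iop_clamp("artery"),
#'                       seed = 7)
#' rec$segment_map
#' @export
apply_protocol <- function(baseline_scene, timeline, seed,
                           cfg = acquisition_config()) {
  stopifnot(inherits(timeline, "ldf_timeline"), nrow(timeline) >= 1)
  frame_s <- cfg$frame_length / cfg$sampling_rate
  base_truth <- scene_truth(baseline_scene, cfg)
  segs <- vector("list", nrow(timeline))
  map <- vector("list", nrow(timeline))
  t0 <- 0
  for (i in seq_len(nrow(timeline))) {
    seg <- timeline[i, ]
    dur <- round(seg$duration / frame_s) * frame_s
    sc <- attenuate_scene(baseline_scene, seg$vel_attenuation,
                          seg$vol_attenuation, cfg)
    rec_i <- synthesize_record(sc$scene, dur, derive_seed(seed, i), cfg)
    segs[[i]] <- rec_i$samples
    map[[i]] <- tibble::tibble(
      label = seg$label, t_start = t0, t_end = t0 + dur,
      vel_attenuation = seg$vel_attenuation,
      vol_attenuation = seg$vol_attenuation,
      vel_true = rec_i$truth$vel_true, vol_true = rec_i$truth$vol_true,
      clamped = sc$clamped
    )
    t0 <- t0 + dur
  }
  structure(
    list(
      samples = unlist(segs, use.names = FALSE),
      sampling_rate = cfg$sampling_rate,
      duration = t0,
      scene = baseline_scene,
      seed = as.integer(seed),
      truth = base_truth,
      segment_map = dplyr::bind_rows(map)
    ),
    class = "ldf_record"
  )
}

# Attenuate a scene's target first moment and modulation depth; falls back to
# a zero-Doppler floor scene when the target is unattainable.
attenuate_scene <- function(scene, vel_f, vol_f, cfg) {
  clamped <- FALSE
  sc <- if (vel_f == 1) {
    scene
  } else if (scene$kind %in% c("wheel", "capillary")) {
    new_speed <- scene$speed * vel_f
    if (scene$k_cal * new_speed <= cfg$analysis_band[1] + 2 * cfg$df) {
      clamped <- TRUE
      fl <- scene; fl$modulation_depth <- 0; fl$floor <- TRUE
      fl
    } else if (scene$kind == "wheel") {
      scene_wheel(new_speed, scene$k_cal, scene$modulation_depth,
                  scene$dc_level, scene$detector_noise_psd, scene$sigma0,
                  scene$broadening_coeff, cfg)
    } else {
      scene_capillary(new_speed, scene$k_cal, scene$modulation_depth,
                      scene$dc_level, scene$detector_noise_psd,
                      scene$sigma0, cfg)
    }
  } else {
    out <- scene_with_target(scene, scene$target_mean_shift * vel_f, cfg)
    clamped <- isTRUE(out$floor) || isTRUE(out$clamped)
    out
  }
  sc$modulation_depth <- sc$modulation_depth * vol_f
  if (sc$modulation_depth == 0) clamped <- clamped || vol_f == 0
  list(scene = sc, clamped = clamped)
}
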