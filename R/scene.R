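#' Scene models: what the laser beam probes
#'
#' A scene is a parametric description of the moving scatterers in the probed
#' volume, from which a one-sided Doppler power spectral density (PSD) of the
#' photocurrent AC component follows analytically:
#'
#' * `scene_wheel()` — a rotating solid surface. A narrow Gaussian Doppler
#'   line centred at `k_cal * speed`, with standard deviation
#'   `sigma0 + broadening_coeff * speed` (an instrumental line-width floor
#'   plus speed-proportional broadening from multiple scattering).
#' * `scene_capillary()` — microspheres in laminar (Poiseuille) capillary
#'   flow. The parabolic velocity profile yields a uniform distribution of
#'   scatterer speeds between 0 and twice the mean, hence a flat spectrum on
#'   `[0, 2 * k_cal * speed]`, convolved with a Gaussian kernel of width
#'   `sigma0`.
#' * `scene_artery()` — a retinal artery. Broadband spectrum modelled as a
#'   truncated exponential `exp(-f / tau)`, with `tau` solved so the
#'   band-limited first moment equals `target_mean_shift`.
#' * `scene_onh()` — optic nerve head. A mixture of a low-frequency
#'   Lorentzian (quasi-elastic tissue scattering, weight `tissue_fraction`)
#'   and an exponential capillary-blood term; a common scale factor on both
#'   widths is solved for the requested band-limited first moment.
#'
#' The calibration constant `k_cal` maps scatterer speed (mm/s) to Doppler
#' shift (Hz); its default, 651/24 ~ 27.1 Hz/(mm/s), equates the instrument's
#' arterial baseline first moment (651 Hz) with the accepted red-blood-cell
#' speed in rat retinal arteries (24 mm/s).
#'
#' `modulation_depth` (beta) is the fraction of DC-squared carried as Doppler
#' AC power; `dc_level` is the mean photodetector output in volts;
#' `detector_noise_psd` is the white detector/shot-noise level in V^2/Hz.
#'
#' @param speed Scatterer speed, mm/s (wheel: surface speed; capillary: mean
#'   flow speed).
#' @param target_mean_shift Target band-limited first moment of the PSD, Hz
#'   (artery/ONH scenes).
#' @param k_cal Calibration constant, Hz per mm/s.
#' @param modulation_depth Fraction of `dc_level^2` carried as Doppler AC
#'   power, in (0, 1).
#' @param dc_level Mean photodetector output, volts.
#' @param detector_noise_psd One-sided white-noise PSD, V^2/Hz.
#' @param sigma0 Line-width floor (wheel) / laminar-edge smoothing kernel
#'   width (capillary), Hz.
#' @param broadening_coeff Speed-proportional line broadening, Hz per mm/s
#'   (wheel only).
#' @param tissue_fraction ONH only: weight of the tissue Lorentzian component.
#' @param tissue_gamma0 ONH only: Lorentzian half-width at unit scale, Hz.
#' @param blood_tau0 ONH only: exponential rate of the blood component at
#'   unit scale, Hz.
#' @param cfg An [acquisition_config()]; scenes that must be solved for a
#'   target first moment validate the target against its analysis band.
#'
#' @return An object of class `ldf_scene`.
#' @examples
#' sc <- scene_wheel(speed = 10)
#' sc$centre_freq # 271.25 Hz
#' art <- scene_artery(651)
#' @name ldf_scene
NULL

default_k_cal <- function() 651 / 24

new_scene <- function(kind, fields) {
  sc <- c(list(kind = kind), fields)
  stopifnot(
    sc$k_cal > 0,
    sc$modulation_depth >= 0, sc$modulation_depth < 1,
    sc$dc_level > 0,
    sc$detector_noise_psd >= 0
  )
  structure(sc, class = "ldf_scene")
}

#' @rdname ldf_scene
#' @export
scene_wheel <- function(speed, k_cal = default_k_cal(),
                        modulation_depth = 0.232, dc_level = 0.359,
                        detector_noise_psd = 1e-8,
                        sigma0 = 20, broadening_coeff = 0.5,
                        cfg = acquisition_config()) {
  stopifnot(speed > 0, sigma0 >= 0, broadening_coeff >= 0)
  centre <- k_cal * speed
  if (centre > cfg$analysis_band[2]) {
    stop("wheel Doppler line at ", round(centre, 1),
         " Hz lies above the analysis band upper edge (",
         cfg$analysis_band[2], " Hz); reduce the speed", call. = FALSE)
  }
  new_scene("wheel", list(
    speed = speed, k_cal = k_cal, modulation_depth = modulation_depth,
    dc_level = dc_level, detector_noise_psd = detector_noise_psd,
    sigma0 = sigma0, broadening_coeff = broadening_coeff,
    centre_freq = centre, line_sd = sigma0 + broadening_coeff * speed
  ))
}

#' @rdname ldf_scene
#' @export
scene_capillary <- function(speed, k_cal = default_k_cal(),
                            modulation_depth = 0.258, dc_level = 0.338,
                            detector_noise_psd = 1e-8,
                            sigma0 = 20,
                            cfg = acquisition_config()) {
  stopifnot(speed > 0, sigma0 > 0)
  mean_shift <- k_cal * speed
  if (mean_shift > cfg$analysis_band[2]) {
    stop("capillary mean Doppler shift ", round(mean_shift, 1),
         " Hz lies above the analysis band upper edge (",
         cfg$analysis_band[2], " Hz); reduce the speed", call. = FALSE)
  }
  new_scene("capillary", list(
    speed = speed, k_cal = k_cal, modulation_depth = modulation_depth,
    dc_level = dc_level, detector_noise_psd = detector_noise_psd,
    sigma0 = sigma0, mean_shift = mean_shift
  ))
}

#' @rdname ldf_scene
#' @export
scene_artery <- function(target_mean_shift = 651, k_cal = default_k_cal(),
                         modulation_depth = 0.20, dc_level = 0.35,
                         detector_noise_psd = 1e-8,
                         cfg = acquisition_config()) {
  tau <- solve_spectrum_rate(target_mean_shift, cfg$analysis_band)
  new_scene("artery", list(
    target_mean_shift = target_mean_shift, k_cal = k_cal,
    modulation_depth = modulation_depth, dc_level = dc_level,
    detector_noise_psd = detector_noise_psd, tau = tau
  ))
}

#' @rdname ldf_scene
#' @export
scene_onh <- function(target_mean_shift = 369, k_cal = default_k_cal(),
                      modulation_depth = 0.15, dc_level = 0.35,
                      detector_noise_psd = 1e-8,
                      tissue_fraction = 0.6, tissue_gamma0 = 50,
                      blood_tau0 = 400, clamp = FALSE,
                      cfg = acquisition_config()) {
  stopifnot(tissue_fraction >= 0, tissue_fraction < 1,
            tissue_gamma0 > 0, blood_tau0 > 0)
  scale <- solve_onh_scale(target_mean_shift, cfg$analysis_band,
                           tissue_fraction, tissue_gamma0, blood_tau0,
                           clamp = clamp)
  new_scene("onh", list(
    target_mean_shift = target_mean_shift, k_cal = k_cal,
    modulation_depth = modulation_depth, dc_level = dc_level,
    detector_noise_psd = detector_noise_psd,
    tissue_fraction = tissue_fraction, tissue_gamma0 = tissue_gamma0,
    blood_tau0 = blood_tau0, scale = as.numeric(scale),
    clamped = isTRUE(attr(scale, "clamped"))
  ))
}

#' @export
print.ldf_scene <- function(x, ...) {
  cat("<ldf_scene:", x$kind, ">\n")
  flds <- x[setdiff(names(x), "kind")]
  for (nm in names(flds)) {
    cat(sprintf("  %-18s %s\n", nm, format(flds[[nm]], digits = 6)))
  }
  invisible(x)
}

# One-sided, unit-area spectral shape of a scene, evaluated at f >= 0.
# Negative-frequency mass of symmetric component densities is folded onto
# f >= 0 so the one-sided shape integrates to 1 on [0, Inf).
scene_shape <- function(scene, f) {
  switch(scene$kind,
    wheel = {
      mu <- scene$centre_freq
      sd <- max(scene$line_sd, 1e-9)
      stats::dnorm(f, mu, sd) + stats::dnorm(-f, mu, sd)
    },
    capillary = {
      hi <- 2 * scene$mean_shift # laminar profile: speeds uniform on [0, 2v]
      s0 <- scene$sigma0
      d <- (stats::pnorm(f, 0, s0) - stats::pnorm(f, hi, s0)) / hi
      dneg <- (stats::pnorm(-f, 0, s0) - stats::pnorm(-f, hi, s0)) / hi
      d + dneg
    },
    artery = exp(-f / scene$tau) / scene$tau,
    onh = {
      g <- scene$tissue_gamma0 * scene$scale
      tau <- scene$blood_tau0 * scene$scale
      tis <- (2 / pi) * g / (f^2 + g^2)
      blo <- exp(-f / tau) / tau
      scene$tissue_fraction * tis + (1 - scene$tissue_fraction) * blo
    },
    stop("unknown scene kind: ", scene$kind, call. = FALSE)
  )
}

# Band-limited zeroth and first moments of the unit-area shape over [lo, hi].
# The wheel's Gaussian line is handled in closed form (truncated-normal
# moments) so arbitrarily narrow lines - down to sigma = 0, a pure tone -
# stay exact; other shapes use trapezoid quadrature on a fine grid.
shape_band_stats <- function(scene, lo, hi, n = 20001L) {
  if (scene$kind == "wheel") return(gaussian_band_stats(scene, lo, hi))
  f <- seq(lo, hi, length.out = n)
  s <- scene_shape(scene, f)
  h <- f[2] - f[1]
  w <- rep(1, n); w[c(1, n)] <- 0.5
  m0 <- sum(w * s) * h
  m1 <- sum(w * f * s) * h
  list(power = m0, moment = if (m0 > 0) m1 / m0 else NA_real_)
}

gaussian_band_stats <- function(scene, lo, hi) {
  mu <- scene$centre_freq
  sd <- scene$line_sd
  if (sd <= 0) {
    inside <- mu >= lo && mu <= hi
    return(list(power = as.numeric(inside),
                moment = if (inside) mu else NA_real_))
  }
  # direct part N(mu, sd) on [lo, hi] plus the folded negative-frequency part
  seg <- function(a, b, m) {
    al <- (a - m) / sd; be <- (b - m) / sd
    p <- stats::pnorm(be) - stats::pnorm(al)
    m1 <- m * p - sd * (stats::dnorm(be) - stats::dnorm(al))
    c(p = p, m1 = m1)
  }
  direct <- seg(lo, hi, mu)
  folded <- seg(-hi, -lo, mu) # mass of N(mu, sd) that folds onto [lo, hi]
  p <- direct[["p"]] + folded[["p"]]
  m1 <- direct[["m1"]] - folded[["m1"]] # folded frequencies appear as -f
  list(power = p, moment = if (p > 0) m1 / p else NA_real_)
}

#' Band-limited first moment of a scene's Doppler spectrum
#'
#' The noise-free ground truth against which pipeline estimates are compared:
#' the power-weighted mean frequency of the scene's PSD restricted to the
#' analysis band, computed by numerical quadrature.
#'
#' @param scene An [ldf_scene].
#' @param cfg An [acquisition_config()].
#' @return A list with `vel_true` (Hz), `vol_true` (a.u.: in-band AC power /
#'   `dc_level^2`) and `dc_true` (volts).
#' @export
scene_truth <- function(scene, cfg = acquisition_config()) {
  band <- cfg$analysis_band
  if (scene$modulation_depth == 0) {
    # no Doppler power: the pipeline reports Vel = 0 with an invalid flag
    return(list(vel_true = 0, vol_true = 0, dc_true = scene$dc_level))
  }
  bs <- shape_band_stats(scene, band[1], band[2])
  total <- shape_band_stats(scene, 0, cfg$nyquist)$power
  list(
    vel_true = bs$moment,
    vol_true = scene$modulation_depth * bs$power / total,
    dc_true = scene$dc_level
  )
}

#' Target power spectral density of a scene
#'
#' Evaluates the scene's one-sided PSD on the frame-spectrum bin grid over the
#' analysis band, normalised so the total AC power over `[0, Nyquist]` equals
#' `modulation_depth * dc_level^2`.
#'
#' @inheritParams scene_truth
#' @return A tibble with columns `frequency` (Hz, bin centres) and `psd`
#'   (V^2/Hz).
#' @examples
#' ts <- target_spectrum(scene_wheel(10), acquisition_config())
#' ts$frequency[which.max(ts$psd)] # near 271 Hz
#' @export
target_spectrum <- function(scene, cfg = acquisition_config()) {
  f <- bin_frequencies(cfg)
  band <- cfg$analysis_band
  keep <- f >= band[1] & f <= band[2]
  scale <- scene_psd_scale(scene, cfg)
  tibble::tibble(frequency = f[keep],
                 psd = scale * scene_shape(scene, f[keep]))
}

# Multiplier turning the unit-area shape into a PSD with total power
# beta * dc^2 on [0, Nyquist].
scene_psd_scale <- function(scene, cfg) {
  total <- shape_band_stats(scene, 0, cfg$nyquist)$power
  scene$modulation_depth * scene$dc_level^2 / total
}

#' Solve the exponential spectral rate for a target first moment
#'
#' Finds `tau` such that the first moment of `exp(-f / tau)` restricted to
#' `band` equals `target_mean_shift`. The band-limited moment is strictly
#' increasing in `tau`, from the band's lower edge (`tau -> 0`) to the band
#' midpoint (`tau -> Inf`, flat-spectrum limit), so bisection applies.
#'
#' @param target_mean_shift Desired band-limited first moment, Hz.
#' @param band Numeric length-2 frequency band, Hz.
#' @param tol Convergence tolerance on the achieved moment, Hz.
#' @return `tau` in Hz.
#' @examples
#' tau <- solve_spectrum_rate(651, c(28, 5012))
#' @export
solve_spectrum_rate <- function(target_mean_shift, band, tol = 0.05) {
  lo <- band[1]; hi <- band[2]
  mid <- (lo + hi) / 2
  if (!is.finite(target_mean_shift) || target_mean_shift <= lo ||
      target_mean_shift >= mid) {
    stop("target first moment ", target_mean_shift,
         " Hz is unattainable for a truncated exponential on [", lo, ", ", hi,
         "] Hz; attainable range is (", lo, ", ", mid, ")", call. = FALSE)
  }
  f <- function(tau) exp_band_moment(tau, lo, hi) - target_mean_shift
  start <- max(target_mean_shift - lo, 1)
  lo_tau <- start / 2
  hi_tau <- start * 2
  while (f(lo_tau) > 0) lo_tau <- lo_tau / 2
  while (f(hi_tau) < 0) hi_tau <- hi_tau * 2
  stats::uniroot(f, c(lo_tau, hi_tau), tol = tol / 10)$root
}

# Closed-form band-limited first moment of exp(-f/tau) on [a, b].
exp_band_moment <- function(tau, a, b) {
  u <- a / tau; v <- b / tau
  # m0 = tau (e^-u - e^-v); m1 = tau^2 [(u+1)e^-u - (v+1)e^-v]
  # ratio written against e^-u to stay stable for small u - v
  d <- -expm1(u - v) # 1 - e^{-(v-u)}
  if (d <= 0) return((a + b) / 2)
  m1_over <- tau * ((u + 1) - (v + 1) * exp(u - v))
  m1_over / d
}

# Common-scale solve for the ONH tissue/blood mixture: both component widths
# are multiplied by one scale factor. Because the Lorentzian's 1/f^2 tail
# keeps band-limited mass (with a ~145 Hz moment for this band) long after
# the exponential component has left the band, the band-limited moment is
# NOT monotone in the scale: it falls from the Lorentzian limit, reaches an
# attainable minimum (~70 Hz for the defaults) and then rises. The solve
# therefore scans a cached log-grid of scales, brackets the target on the
# largest-scale branch, and refines by uniroot. With `clamp = TRUE` a target
# below the attainable minimum returns the minimising scale flagged via the
# "clamped" attribute instead of an error.
onh_moment_env <- new.env(parent = emptyenv())

onh_moment_curve <- function(band, tissue_fraction, gamma0, tau0) {
  key <- paste(band[1], band[2], tissue_fraction, gamma0, tau0, sep = "|")
  cached <- onh_moment_env[[key]]
  if (!is.null(cached)) return(cached)
  s_grid <- 10^seq(-4, 2, length.out = 181)
  m <- vapply(s_grid, function(s) {
    onh_band_moment(s, band, tissue_fraction, gamma0, tau0)
  }, numeric(1))
  out <- list(s = s_grid, moment = m)
  onh_moment_env[[key]] <- out
  out
}

onh_band_moment <- function(s, band, tissue_fraction, gamma0, tau0) {
  sc <- structure(list(kind = "onh", tissue_fraction = tissue_fraction,
                       tissue_gamma0 = gamma0, blood_tau0 = tau0,
                       scale = s), class = "ldf_scene")
  shape_band_stats(sc, band[1], band[2], n = 8001L)$moment
}

solve_onh_scale <- function(target, band, tissue_fraction, gamma0, tau0,
                            clamp = FALSE) {
  if (!is.finite(target) || target <= band[1]) {
    stop("ONH target first moment ", target,
         " Hz is at or below the analysis band lower edge (", band[1],
         " Hz)", call. = FALSE)
  }
  curve <- onh_moment_curve(band, tissue_fraction, gamma0, tau0)
  if (target >= max(curve$moment)) {
    stop("ONH target first moment ", target,
         " Hz is unattainable for this mixture (maximum ~",
         round(max(curve$moment)), " Hz)", call. = FALSE)
  }
  if (target <= min(curve$moment)) {
    if (clamp) {
      s_min <- curve$s[which.min(curve$moment)]
      return(structure(s_min, clamped = TRUE,
                       achieved = min(curve$moment)))
    }
    stop("ONH target first moment ", target,
         " Hz is below the attainable minimum for this mixture (~",
         round(min(curve$moment)), " Hz); use a larger target",
         call. = FALSE)
  }
  diffs <- curve$moment - target
  idx <- which(diffs[-length(diffs)] * diffs[-1] <= 0)
  i <- idx[length(idx)] # largest-scale (broadest-spectrum) branch
  root <- stats::uniroot(
    function(s) onh_band_moment(s, band, tissue_fraction, gamma0, tau0) - target,
    c(curve$s[i], curve$s[i + 1]), tol = 1e-7
  )$root
  structure(root, clamped = FALSE)
}

# Rebuild a solvable scene (artery/onh) at a new target first moment, or
# return a "floor" scene (zero Doppler power) when the target has fallen
# below the attainable range -- used by protocol simulation when perfusion
# is driven to a halt.
scene_with_target <- function(scene, new_target, cfg) {
  floor_edge <- cfg$analysis_band[1] + 2 * cfg$df
  make_floor <- function() {
    sc <- scene
    sc$modulation_depth <- 0
    sc$floor <- TRUE
    sc
  }
  out <- switch(scene$kind,
    artery = {
      if (new_target <= floor_edge) make_floor()
      else {
        sc <- scene
        sc$target_mean_shift <- new_target
        sc$tau <- solve_spectrum_rate(new_target, cfg$analysis_band)
        sc
      }
    },
    onh = {
      if (new_target <= floor_edge) make_floor()
      else {
        sc <- scene
        sc$target_mean_shift <- new_target
        scale <- solve_onh_scale(new_target, cfg$analysis_band,
                                 scene$tissue_fraction,
                                 scene$tissue_gamma0, scene$blood_tau0,
                                 clamp = TRUE)
        sc$scale <- as.numeric(scale)
        sc$clamped <- isTRUE(attr(scale, "clamped"))
        sc
      }
    },
    stop("scene kind ", scene$kind,
         " has no target first moment to re-solve", call. = FALSE)
  )
  out
}
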