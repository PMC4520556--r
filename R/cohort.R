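#' Cohort parameters for synthetic rat populations
#'
#' Describes the between-animal and within-animal variance structure of
#' baseline Doppler velocity at a measurement site. Defaults reproduce the
#' instrument's in-vivo calibration: retinal-artery baseline first moment
#' 651 +/- 76 Hz and optic-nerve-head 369 +/- 138 Hz (mean +/- between-rat
#' SD). The within-animal components are derived from the published
#' repeatability coefficients via [calibrate_variance_components()]:
#' `sd_session` from the inter-session ICC (0.82 artery / 0.87 ONH),
#' `sd_minute` from the intra-session ICC (0.4 / 0.6) and `sd_reposition`
#' (an extra beam-repositioning offset applied on a later measurement day)
#' from the inter-day ICC (0.79 / 0.7).
#'
#' @param site `"artery"` or `"onh"`.
#' @param n_rats Number of animals.
#' @param mean_baseline Population mean baseline first moment, Hz.
#' @param sd_between Between-rat SD, Hz.
#' @param sd_session Between-session SD within rat, Hz.
#' @param sd_minute Stationary SD of minute-scale AR(1) fluctuation, Hz.
#' @param sd_reposition SD of the day-to-day beam-repositioning offset, Hz.
#' @param ar1_minute Lag-1 autocorrelation of the minute-scale fluctuation.
#' @return An object of class `ldf_cohort_params`.
#' @examples
#' cohort_params("artery", n_rats = 12)
#' @export
cohort_params <- function(site = c("artery", "onh"), n_rats = 12,
                          mean_baseline = NULL, sd_between = NULL,
                          sd_session = NULL, sd_minute = NULL,
                          sd_reposition = NULL, ar1_minute = 0.5) {
  site <- match.arg(site)
  def <- switch(site,
    artery = list(mean = 651, sd_b = 76,
                  icc = c(intra = 0.40, inter_session = 0.82, inter_day = 0.79)),
    onh = list(mean = 369, sd_b = 138,
               icc = c(intra = 0.60, inter_session = 0.87, inter_day = 0.70))
  )
  mean_baseline <- mean_baseline %||% def$mean
  sd_between <- sd_between %||% def$sd_b
  cal <- calibrate_variance_components(
    sd_between,
    icc_intrasession = def$icc[["intra"]],
    icc_intersession = def$icc[["inter_session"]],
    icc_interday = def$icc[["inter_day"]]
  )
  p <- list(
    site = site, n_rats = as.integer(n_rats),
    mean_baseline = mean_baseline, sd_between = sd_between,
    sd_session = sd_session %||% cal$sd_session,
    sd_minute = sd_minute %||% cal$sd_minute,
    sd_reposition = sd_reposition %||% cal$sd_reposition,
    ar1_minute = ar1_minute
  )
  stopifnot(p$n_rats >= 2, p$mean_baseline > 0, p$sd_between >= 0,
            p$sd_session >= 0, p$sd_minute >= 0, p$sd_reposition >= 0,
            abs(p$ar1_minute) < 1)
  structure(p, class = "ldf_cohort_params")
}

#' @export
print.ldf_cohort_params <- function(x, ...) {
  cat("<ldf_cohort_params>", x$site, "site,", x$n_rats, "rats\n")
  cat(sprintf("  baseline %g +/- %g Hz | sd_session %.1f | sd_minute %.1f | sd_reposition %.1f Hz | minute AR(1) rho %.2f\n",
              x$mean_baseline, x$sd_between, x$sd_session, x$sd_minute,
              x$sd_reposition, x$ar1_minute))
  invisible(x)
}

#' Derive within-animal SDs from target intraclass correlations
#'
#' Inverts the variance-components identity `ICC = sigma_b^2 / (sigma_b^2 +
#' sigma_w^2)` at each timescale of a nested repeated-measures design:
#'
#' * inter-session: session means differ by the session effect only, so
#'   `sd_session = sd_between * sqrt((1 - ICC) / ICC)`;
#' * intra-session: within one session the rat and session effects act
#'   together as the "subject" level, so `sd_minute = sqrt((sd_between^2 +
#'   sd_session^2) * (1 - ICC) / ICC)`;
#' * inter-day: the day-to-day comparison adds a beam-repositioning offset on
#'   top of the session effect, `sd_reposition = sqrt(max(sd_between^2 *
#'   (1 - ICC) / ICC - sd_session^2, 0))`.
#'
#' @param sd_between Between-rat SD, Hz.
#' @param icc_intrasession,icc_intersession,icc_interday Target ICCs in
#'   (0, 1].
#' @return A list with `sd_session`, `sd_minute`, `sd_reposition` (Hz) and
#'   the implied theoretical ICCs (`icc_theoretical`).
#' @examples
#' calibrate_variance_components(76, 0.40, 0.82, 0.79)
#' @export
calibrate_variance_components <- function(sd_between, icc_intrasession,
                                          icc_intersession, icc_interday) {
  stopifnot(sd_between >= 0,
            icc_intrasession > 0, icc_intrasession <= 1,
            icc_intersession > 0, icc_intersession <= 1,
            icc_interday > 0, icc_interday <= 1)
  vb <- sd_between^2
  vs <- vb * (1 - icc_intersession) / icc_intersession
  vm <- (vb + vs) * (1 - icc_intrasession) / icc_intrasession
  vr <- max(vb * (1 - icc_interday) / icc_interday - vs, 0)
  list(
    sd_session = sqrt(vs),
    sd_minute = sqrt(vm),
    sd_reposition = sqrt(vr),
    icc_theoretical = c(
      intrasession = (vb + vs) / (vb + vs + vm),
      intersession = vb / (vb + vs),
      interday = vb / (vb + vs + vr)
    )
  )
}

#' Sample a synthetic cohort's measurement targets
#'
#' Draws, for each rat, session and minute, the target band-limited first
#' moment the laser sees during that minute of recording:
#'
#' * rat baseline `f_i ~ Normal(mean_baseline, sd_between^2)`, truncated
#'   above the analysis band's lower edge;
#' * on days after the first, a per-day repositioning offset
#'   `Normal(0, sd_reposition^2)`;
#' * session target `f_ij = f_i (+ offset) + Normal(0, sd_session^2)`;
#' * minute targets add an AR(1) fluctuation with stationary SD `sd_minute`
#'   and lag-1 correlation `ar1_minute`, centred within the session so the
#'   session's mean target carries only the rat, day and session components.
#'
#' Targets are floored at three bin widths above the band's lower edge so
#' every minute's spectrum stays solvable.
#'
#' @param params An [cohort_params()] object.
#' @param sessions Sessions per day.
#' @param minutes_per_session Minute-scale segments per session (a 10-s
#'   recording is a single segment).
#' @param days Number of measurement days.
#' @param seed Integer root seed; every rat/day/session draws through
#'   deterministic child seeds, so cohorts are reproducible piecewise.
#' @param cfg An [acquisition_config()].
#' @return A tibble with one row per (rat, day, session, minute):
#'   `rat`, `day`, `session`, `minute`, `rat_baseline`, `session_target`,
#'   `target` (Hz), `record_seed` (per rat-day-session child seed).
#' @examples
#' ch <- sample_cohort(cohort_params("artery", n_rats = 4), seed = 1)
#' head(ch)
#' @export
sample_cohort <- function(params, sessions = 3, minutes_per_session = 5,
                          days = 1, seed = 1,
                          cfg = acquisition_config()) {
  stopifnot(inherits(params, "ldf_cohort_params"), params$n_rats >= 2,
            sessions >= 1, minutes_per_session >= 1, days >= 1)
  floor_hz <- cfg$analysis_band[1] + 3 * cfg$df
  rows <- list()
  for (i in seq_len(params$n_rats)) {
    f_i <- withr::with_seed(derive_seed(seed, i, 0, 0), {
      x <- stats::rnorm(1, params$mean_baseline, params$sd_between)
      tries <- 0
      while (x <= floor_hz && tries < 1000) {
        x <- stats::rnorm(1, params$mean_baseline, params$sd_between)
        tries <- tries + 1
      }
      max(x, floor_hz + cfg$df)
    })
    for (d in seq_len(days)) {
      repo <- if (d == 1) 0 else withr::with_seed(
        derive_seed(seed, i, d, 0, 1),
        stats::rnorm(1, 0, params$sd_reposition)
      )
      for (j in seq_len(sessions)) {
        dev <- withr::with_seed(derive_seed(seed, i, d, j), {
          sess <- stats::rnorm(1, 0, params$sd_session)
          m <- ar1_series(minutes_per_session, params$sd_minute,
                          params$ar1_minute)
          list(sess = sess, minute = m - mean(m))
        })
        f_ij <- f_i + repo + dev$sess
        rows[[length(rows) + 1L]] <- tibble::tibble(
          rat = i, day = d, session = j,
          minute = seq_len(minutes_per_session),
          rat_baseline = f_i,
          session_target = f_ij,
          target = pmax(f_ij + dev$minute, floor_hz),
          record_seed = derive_seed(seed, i, d, j, 99)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- params
  out
}

# Stationary AR(1) series of length n with marginal SD sigma.
ar1_series <- function(n, sigma, rho) {
  if (sigma == 0 || n == 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  if (n > 1) {
    eps <- stats::rnorm(n - 1, 0, sigma * sqrt(1 - rho^2))
    for (t in 2:n) x[t] <- rho * x[t - 1] + eps[t - 1]
  }
  x
}

#' Synthesize one session recording for a sampled cohort row-set
#'
#' Builds the piecewise-stationary record for one rat-session: consecutive
#' minute segments, each an artery/ONH scene re-solved at that minute's
#' target. `segment_duration` trims the final segment so short (scaled-down)
#' recordings are possible.
#'
#' @param session_rows The rows of a [sample_cohort()] tibble belonging to a
#'   single rat/day/session, in minute order.
#' @param site `"artery"` or `"onh"`.
#' @param total_duration Total recording length, s (default 60 s per minute
#'   row).
#' @param cfg An [acquisition_config()].
#' @param ... Passed to [scene_artery()]/[scene_onh()] (e.g. modulation
#'   depth overrides).
#' @return An `ldf_record` with a per-minute `segment_map`.
#' @export
synthesize_session <- function(session_rows, site = c("artery", "onh"),
                               total_duration = 60 * nrow(session_rows),
                               cfg = acquisition_config(), ...) {
  site <- match.arg(site)
  stopifnot(nrow(session_rows) >= 1, total_duration > 0)
  frame_s <- cfg$frame_length / cfg$sampling_rate
  seed <- session_rows$record_seed[1]
  remaining <- round(total_duration / frame_s) * frame_s
  segs <- list(); map <- list(); t0 <- 0
  for (k in seq_len(nrow(session_rows))) {
    if (remaining <= 0) break
    dur <- min(round(60 / frame_s) * frame_s, remaining)
    remaining <- remaining - dur
    sc <- if (site == "artery") {
      scene_artery(session_rows$target[k], cfg = cfg, ...)
    } else {
      scene_onh(session_rows$target[k], cfg = cfg, clamp = TRUE, ...)
    }
    rec_k <- synthesize_record(sc, dur, derive_seed(seed, k), cfg)
    segs[[k]] <- rec_k$samples
    map[[k]] <- tibble::tibble(
      label = paste0("minute_", session_rows$minute[k]),
      t_start = t0, t_end = t0 + dur,
      vel_attenuation = NA_real_, vol_attenuation = NA_real_,
      vel_true = rec_k$truth$vel_true, vol_true = rec_k$truth$vol_true,
      clamped = FALSE
    )
    t0 <- t0 + dur
  }
  base_scene <- if (site == "artery") {
    scene_artery(max(session_rows$session_target[1],
                     cfg$analysis_band[1] + 3 * cfg$df), cfg = cfg, ...)
  } else {
    scene_onh(max(session_rows$session_target[1],
                  cfg$analysis_band[1] + 3 * cfg$df),
              cfg = cfg, clamp = TRUE, ...)
  }
  structure(
    list(
      samples = unlist(segs, use.names = FALSE),
      sampling_rate = cfg$sampling_rate,
      duration = t0,
      scene = base_scene,
      seed = as.integer(seed),
      truth = scene_truth(base_scene, cfg),
      segment_map = dplyr::bind_rows(map)
    ),
    class = "ldf_record"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
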