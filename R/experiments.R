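#' Bench linearity experiment
#'
#' Reproduces the bench validation of the flowmeter: the scene (rotating
#' Teflon wheel or capillary microsphere flow) is stepped through a series of
#' speeds; at each speed a 40-s record is synthesized, processed and
#' averaged, and the Pearson correlation of mean velocity against speed is
#' computed, together with a least-squares line and the flatness (CV across
#' speeds) of Vol and DC.
#'
#' @param scene_kind `"wheel"` or `"capillary"`.
#' @param speeds At least 4 speeds, mm/s. Wheel speeds must be >= 5 mm/s
#'   (the bench motor's floor); capillary speeds within [0.3, 50] mm/s (the
#'   validated range).
#' @param seed Integer root seed.
#' @param cfg An [acquisition_config()].
#' @param duration Record length per speed, s (default 40).
#' @param ... Scene parameter overrides passed to [scene_wheel()] /
#'   [scene_capillary()] (e.g. `sigma0`, `detector_noise_psd`).
#' @return An object of class `ldf_linearity`: list with `summary` (tibble,
#'   one row per speed: `speed`, `vel_true`, `vel_mean`, `vel_sd`,
#'   `vol_mean`, `dc_mean`, `n_valid`), `pearson_r`, `pearson_p`, `slope`
#'   (Hz per mm/s), `intercept` (Hz), `vol_cv`, `dc_cv`, `scene_kind`.
#' @examples
#' \donttest{
#' res <- run_linearity("capillary", c(0.3, 1, 3, 10, 30, 50), seed = 1)
#' glance(res)
#' }
#' @export
run_linearity <- function(scene_kind = c("wheel", "capillary"), speeds,
                          seed = 1, cfg = acquisition_config(),
                          duration = 40, ...) {
  scene_kind <- match.arg(scene_kind)
  if (length(speeds) < 4) stop("need at least 4 speeds", call. = FALSE)
  if (scene_kind == "wheel" && any(speeds < 5)) {
    stop("wheel speeds below the 5 mm/s motor floor are not supported",
         call. = FALSE)
  }
  if (scene_kind == "capillary" && any(speeds < 0.3 | speeds > 50)) {
    stop("capillary speeds must lie within the validated 0.3-50 mm/s range",
         call. = FALSE)
  }
  rows <- purrr::imap(speeds, function(v, i) {
    sc <- if (scene_kind == "wheel") scene_wheel(v, cfg = cfg, ...) else
      scene_capillary(v, cfg = cfg, ...)
    rec <- synthesize_record(sc, duration, derive_seed(seed, i), cfg)
    avg <- average_trace(process_record(rec, cfg), window = duration)
    tibble::tibble(
      speed = v, vel_true = rec$truth$vel_true,
      vel_mean = avg$vel_mean, vel_sd = avg$vel_sd,
      vol_mean = avg$vol_mean, dc_mean = avg$dc_mean,
      n_valid = avg$n_valid
    )
  })
  summary <- dplyr::bind_rows(rows)
  pr <- pearson(summary$speed, summary$vel_mean)
  fit <- stats::lm(vel_mean ~ speed, data = summary)
  structure(
    list(
      summary = summary,
      pearson_r = pr$r, pearson_p = pr$p,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      vol_cv = stats::sd(summary$vol_mean) / mean(summary$vol_mean),
      dc_cv = stats::sd(summary$dc_mean) / mean(summary$dc_mean),
      scene_kind = scene_kind, duration = duration, seed = seed
    ),
    class = "ldf_linearity"
  )
}

#' @export
print.ldf_linearity <- function(x, ...) {
  cat("<ldf_linearity>", x$scene_kind, "scene,", nrow(x$summary),
      "speeds,", x$duration, "s per speed\n")
  cat(sprintf("  Pearson r = %.4f (p = %.3g) | slope %.2f Hz/(mm/s), intercept %.1f Hz\n",
              x$pearson_r, x$pearson_p, x$slope, x$intercept))
  cat(sprintf("  Vol CV %.2f%%, DC CV %.2f%% across speeds\n",
              100 * x$vol_cv, 100 * x$dc_cv))
  print(x$summary)
  invisible(x)
}

#' Baseline velocity recovery on a synthetic cohort
#'
#' Samples a cohort from the default (or supplied) population parameters,
#' synthesizes one recording per rat, processes it and summarises the
#' per-rat mean velocity as group mean +/- SD - the synthetic analogue of the
#' physiological baseline characterisation (artery 651 +/- 76 Hz at n = 12;
#' ONH 369 +/- 138 Hz at n = 16).
#'
#' @param site `"artery"` or `"onh"`.
#' @param n_rats Number of animals (>= 2).
#' @param seed Integer root seed.
#' @param cfg An [acquisition_config()].
#' @param duration Per-rat recording length, s (default 300 = 5 min).
#' @param params Optional [cohort_params()] override.
#' @return An object of class `ldf_baseline`: list with `per_rat` (tibble:
#'   `rat`, `target`, `vel_mean`, `vel_sd`, `n_valid`), `mean`, `sd`, `site`,
#'   `n_rats`.
#' @export
run_baseline <- function(site = c("artery", "onh"), n_rats = 12, seed = 1,
                         cfg = acquisition_config(), duration = 300,
                         params = NULL) {
  site <- match.arg(site)
  stopifnot(n_rats >= 2)
  params <- params %||% cohort_params(site, n_rats = n_rats)
  minutes <- max(1L, ceiling(duration / 60))
  cohort <- sample_cohort(params, sessions = 1, minutes_per_session = minutes,
                          days = 1, seed = seed, cfg = cfg)
  per_rat <- cohort |>
    dplyr::group_by(.data$rat) |>
    dplyr::group_map(function(rows, key) {
      rec <- synthesize_session(rows, site, total_duration = duration,
                                cfg = cfg)
      avg <- average_trace(process_record(rec, cfg),
                          window = rec$duration)
      tibble::tibble(rat = key$rat, target = rows$session_target[1],
                     vel_mean = avg$vel_mean, vel_sd = avg$vel_sd,
                     n_valid = avg$n_valid)
    }) |>
    dplyr::bind_rows()
  structure(
    list(per_rat = per_rat,
         mean = mean(per_rat$vel_mean), sd = stats::sd(per_rat$vel_mean),
         site = site, n_rats = n_rats, duration = duration, seed = seed),
    class = "ldf_baseline"
  )
}

#' @export
print.ldf_baseline <- function(x, ...) {
  cat(sprintf("<ldf_baseline> %s site, n = %d rats, %g s records\n",
              x$site, x$n_rats, x$duration))
  cat(sprintf("  group mean Vel %.0f +/- %.0f Hz\n", x$mean, x$sd))
  invisible(x)
}

#' Repeatability study on a synthetic cohort
#'
#' Runs the full repeated-measures design on one synthetic cohort and feeds
#' the resulting tables through [variation_coefficient()] and [icc_a1()]:
#'
#' * intra-session: per-minute means within each recording (computed when
#'   `session_duration >= 120` s so at least two minute windows exist);
#'   ICC/VC are computed per session and averaged across sessions;
#' * inter-session: the `sessions` per-recording means on day 1;
#' * inter-day: day-1 first recording versus the day-8 recording, whose
#'   targets are re-jittered with the session component plus a
#'   beam-repositioning perturbation (`sd_reposition`).
#'
#' @param site `"artery"` or `"onh"`.
#' @param n_rats Number of animals (>= 4 for a stable ANOVA).
#' @param sessions Recordings per day (default 3).
#' @param seed Integer root seed.
#' @param cfg An [acquisition_config()].
#' @param session_duration Per-recording length, s. The in-vivo design used
#'   300 s; scaled-down studies may use 10 s.
#' @param include_interday Also simulate the second measurement day.
#' @param params Optional [cohort_params()] override.
#' @return An object of class `ldf_repeatability`: list with `table_rows`
#'   (tibble: `timescale`, `vc_mean`, `vc_sd`, `icc`, `ci_low`, `ci_high`,
#'   `p`, `agreement`), `session_means` (rats x sessions matrix, day 1) and
#'   `interday_means` (rats x 2, when computed).
#' @export
run_repeatability <- function(site = c("artery", "onh"), n_rats = 6,
                              sessions = 3, seed = 1,
                              cfg = acquisition_config(),
                              session_duration = 300,
                              include_interday = TRUE,
                              params = NULL) {
  site <- match.arg(site)
  stopifnot(n_rats >= 4, sessions >= 2)
  params <- params %||% cohort_params(site, n_rats = n_rats)
  minutes <- max(1L, ceiling(session_duration / 60))
  days <- if (include_interday) 2L else 1L
  cohort <- sample_cohort(params, sessions = sessions,
                          minutes_per_session = minutes, days = days,
                          seed = seed, cfg = cfg)
  session_mean <- function(rows) {
    rec <- synthesize_session(rows, site, total_duration = session_duration,
                              cfg = cfg)
    tr <- process_record(rec, cfg)
    full <- average_trace(tr, window = rec$duration)
    minute_means <- if (session_duration >= 120) {
      average_trace(tr, window = 60)$vel_mean
    } else NULL
    list(mean = full$vel_mean, minutes = minute_means)
  }
  res <- cohort |>
    dplyr::group_by(.data$rat, .data$day, .data$session) |>
    dplyr::group_map(function(rows, key) {
      sm <- session_mean(rows)
      tibble::tibble(rat = key$rat, day = key$day, session = key$session,
                     vel_mean = sm$mean,
                     minutes = list(sm$minutes))
    }) |>
    dplyr::bind_rows()

  day1 <- dplyr::filter(res, .data$day == 1)
  sess_tab <- day1 |>
    dplyr::select("rat", "session", "vel_mean") |>
    tidyr::pivot_wider(names_from = "session", values_from = "vel_mean",
                       names_prefix = "session_") |>
    dplyr::arrange(.data$rat)
  sess_mat <- as.matrix(sess_tab[, -1])
  rownames(sess_mat) <- sess_tab$rat

  rows_out <- list()
  # intra-session: minute-level tables, one per day-1 session, averaged
  if (session_duration >= 120) {
    intra <- purrr::map(seq_len(sessions), function(j) {
      mm <- day1 |> dplyr::filter(.data$session == j) |> dplyr::arrange(.data$rat)
      tab <- do.call(rbind, mm$minutes)
      list(icc = icc_a1(tab), vc = variation_coefficient(tab))
    })
    rows_out$intra <- tibble::tibble(
      timescale = "intra-session",
      vc_mean = mean(purrr::map_dbl(intra, ~ .x$vc$vc_mean)),
      vc_sd = mean(purrr::map_dbl(intra, ~ .x$vc$vc_sd)),
      icc = mean(purrr::map_dbl(intra, ~ .x$icc$icc)),
      ci_low = mean(purrr::map_dbl(intra, ~ .x$icc$ci_low)),
      ci_high = mean(purrr::map_dbl(intra, ~ .x$icc$ci_high)),
      p = mean(purrr::map_dbl(intra, ~ .x$icc$p))
    )
  }
  icc_sess <- icc_a1(sess_mat)
  vc_sess <- variation_coefficient(sess_mat)
  rows_out$inter <- tibble::tibble(
    timescale = "inter-session",
    vc_mean = vc_sess$vc_mean, vc_sd = vc_sess$vc_sd,
    icc = icc_sess$icc, ci_low = icc_sess$ci_low,
    ci_high = icc_sess$ci_high, p = icc_sess$p
  )
  interday_mat <- NULL
  if (include_interday) {
    d1 <- day1 |> dplyr::filter(.data$session == 1) |> dplyr::arrange(.data$rat)
    d8 <- res |> dplyr::filter(.data$day == 2, .data$session == 1) |>
      dplyr::arrange(.data$rat)
    interday_mat <- cbind(day1 = d1$vel_mean, day8 = d8$vel_mean)
    rownames(interday_mat) <- d1$rat
    icc_day <- icc_a1(interday_mat)
    vc_day <- variation_coefficient(interday_mat)
    rows_out$interday <- tibble::tibble(
      timescale = "inter-day",
      vc_mean = vc_day$vc_mean, vc_sd = vc_day$vc_sd,
      icc = icc_day$icc, ci_low = icc_day$ci_low,
      ci_high = icc_day$ci_high, p = icc_day$p
    )
  }
  table_rows <- dplyr::bind_rows(rows_out) |>
    dplyr::mutate(agreement = icc_agreement_label(.data$icc))
  structure(
    list(table_rows = table_rows, session_means = sess_mat,
         interday_means = interday_mat, site = site, n_rats = n_rats,
         sessions = sessions, session_duration = session_duration,
         seed = seed),
    class = "ldf_repeatability"
  )
}

#' @export
print.ldf_repeatability <- function(x, ...) {
  cat(sprintf("<ldf_repeatability> %s site, n = %d rats, %d sessions of %g s\n",
              x$site, x$n_rats, x$sessions, x$session_duration))
  print(x$table_rows)
  invisible(x)
}

#' Perfusion-challenge protocol on a synthetic cohort
#'
#' Simulates either the acute intraocular-hypertension protocol
#' ([timeline_iop_clamp()]: 2 min baseline, 4 min at 150 mmHg, 5 min
#' recovery) or the heart-arrest protocol ([timeline_heart_arrest()]) on
#' `n_rats` animals drawn from the site's cohort distribution. Each rat's
#' record is processed, segment means are taken over quality-valid samples
#' with the first `guard` seconds of each segment dropped as a transition
#' guard, and the per-rat percent decrease (baseline vs intervention) is
#' summarised with an exact Wilcoxon signed-rank test.
#'
#' @param protocol `"iop_clamp"` or `"heart_arrest"`.
#' @param site `"artery"` or `"onh"`.
#' @param n_rats Number of animals (default 5, the in-vivo design).
#' @param seed Integer root seed.
#' @param cfg An [acquisition_config()].
#' @param guard Transition guard dropped at each segment start, s.
#' @param timeline Optional [protocol_timeline()] override.
#' @param params Optional [cohort_params()] override.
#' @return An object of class `ldf_protocol`: list with `per_rat` (tibble:
#'   `rat`, `baseline`, `intervention`, `recovery` (if present),
#'   `percent_change`), `segment_means` (long tibble), `mean_change`,
#'   `sd_change`, `wilcoxon` (tibble `w`, `p`), `protocol`, `site`.
#' @examples
#' \donttest{
#' res <- run_protocol("iop_clamp", "artery", n_rats = 5, seed = 1)
#' glance(res)
#' }
#' @export
run_protocol <- function(protocol = c("iop_clamp", "heart_arrest"),
                         site = c("artery", "onh"), n_rats = 5, seed = 1,
                         cfg = acquisition_config(), guard = 10,
                         timeline = NULL, params = NULL) {
  protocol <- match.arg(protocol)
  site <- match.arg(site)
  stopifnot(n_rats >= 2)
  timeline <- timeline %||% switch(protocol,
    iop_clamp = timeline_iop_clamp(site),
    heart_arrest = timeline_heart_arrest(site)
  )
  params <- params %||% cohort_params(site, n_rats = n_rats)
  cohort <- sample_cohort(params, sessions = 1, minutes_per_session = 1,
                          days = 1, seed = seed, cfg = cfg)
  seg_rows <- purrr::map(seq_len(n_rats), function(i) {
    target <- cohort$session_target[cohort$rat == i]
    sc <- if (site == "artery") scene_artery(target, cfg = cfg) else
      scene_onh(target, clamp = TRUE, cfg = cfg)
    rec <- apply_protocol(sc, timeline, derive_seed(seed, i, 7), cfg)
    tr <- process_record(rec, cfg)
    sm <- rec$segment_map
    purrr::map(seq_len(nrow(sm)), function(s) {
      keep <- tr$time >= sm$t_start[s] + guard & tr$time < sm$t_end[s] &
        tr$valid & tr$quality_ok
      tibble::tibble(rat = i, segment = sm$label[s],
                     vel_mean = mean(tr$vel[keep]),
                     vel_true = sm$vel_true[s],
                     n_valid = sum(keep), clamped = sm$clamped[s])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  labels <- unique(seg_rows$segment)
  wide <- seg_rows |>
    dplyr::select("rat", "segment", "vel_mean") |>
    tidyr::pivot_wider(names_from = "segment", values_from = "vel_mean")
  base_lab <- labels[1]; int_lab <- labels[2]
  per_rat <- wide |>
    dplyr::mutate(percent_change =
                    100 * (.data[[base_lab]] - .data[[int_lab]]) /
                    .data[[base_lab]])
  wx <- wilcoxon_signed_rank(per_rat[[base_lab]], per_rat[[int_lab]])
  structure(
    list(per_rat = per_rat, segment_means = seg_rows,
         mean_change = mean(per_rat$percent_change),
         sd_change = stats::sd(per_rat$percent_change),
         wilcoxon = wx, protocol = protocol, site = site,
         n_rats = n_rats, seed = seed, timeline = timeline),
    class = "ldf_protocol"
  )
}

#' @export
print.ldf_protocol <- function(x, ...) {
  cat(sprintf("<ldf_protocol> %s at %s site, n = %d rats\n",
              x$protocol, x$site, x$n_rats))
  cat(sprintf("  mean Vel decrease %.1f +/- %.1f %% (Wilcoxon W = %g, p = %.4g)\n",
              x$mean_change, x$sd_change, x$wilcoxon$w, x$wilcoxon$p))
  print(x$per_rat)
  invisible(x)
}
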