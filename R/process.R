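#' Cut a record into non-overlapping analysis frames
#'
#' @param record An `ldf_record` (or a bare numeric vector of samples).
#' @param cfg An [acquisition_config()].
#' @return A `frame_length x n_frames` numeric matrix; trailing samples that
#'   do not fill a whole frame are dropped.
#' @examples
#' rec <- synthesize_record(scene_artery(651), duration = 1, seed = 1)
#' dim(frame_signal(rec)) # 1024 x 14
#' @export
frame_signal <- function(record, cfg = acquisition_config()) {
  x <- if (inherits(record, "ldf_record")) record$samples else as.numeric(record)
  n <- length(x)
  if (n < cfg$frame_length) {
    stop("record of ", n, " samples is shorter than one analysis frame (",
         cfg$frame_length, " samples)", call. = FALSE)
  }
  n_frames <- n %/% cfg$frame_length
  matrix(x[seq_len(n_frames * cfg$frame_length)],
         nrow = cfg$frame_length, ncol = n_frames)
}

analysis_window <- function(cfg) {
  n <- cfg$frame_length
  if (cfg$window == "hann") {
    0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  } else {
    rep(1, n)
  }
}

# Vectorised core: one-sided windowed periodograms for a matrix of frames.
# Scaling: sum(power) * df equals the window-power-corrected AC variance
# sum((w * ac)^2) / sum(w^2) of each frame (discrete Parseval identity, with
# the residual windowed-DC term assigned to the excluded 0 Hz bin).
periodograms <- function(frames, cfg) {
  w <- analysis_window(cfg)
  n <- cfg$frame_length
  dc <- colMeans(frames)
  ac <- sweep(frames, 2L, dc)
  ft <- stats::mvfft(ac * w)
  half <- n %/% 2
  p <- Mod(ft[2:(half + 1), , drop = FALSE])^2
  scale <- 2 / (cfg$sampling_rate * sum(w^2))
  p <- p * scale
  p[half, ] <- p[half, ] / 2 # Nyquist bin is not doubled
  freq <- seq_len(half) * cfg$df
  noise_rows <- freq > cfg$noise_band_low_edge
  noise_floor <- colMeans(p[noise_rows, , drop = FALSE])
  list(freq = freq, power = p, dc = dc, noise_floor = noise_floor)
}

#' Power spectrum of a single analysis frame
#'
#' Removes the frame mean (DC), applies the analysis window, and computes the
#' one-sided periodogram scaled to V^2/Hz so that total power times bin width
#' recovers the window-corrected AC variance. The noise floor is the mean raw
#' power over bins strictly above `noise_band_low_edge` (default 4 kHz).
#'
#' @param frame A numeric vector of exactly `frame_length` samples.
#' @param cfg An [acquisition_config()].
#' @return An object of class `ldf_spectrum`: list with `frequency` (Hz, bin
#'   centres 14..Nyquist), `power` (V^2/Hz), `dc` (volts), `noise_floor`
#'   (V^2/Hz).
#' @examples
#' cfg <- acquisition_config()
#' fr <- frame_signal(synthesize_record(scene_artery(651), 1, 1, cfg), cfg)
#' sp <- compute_spectrum(fr[, 1], cfg)
#' @export
compute_spectrum <- function(frame, cfg = acquisition_config()) {
  if (length(frame) != cfg$frame_length) {
    stop("frame must have exactly frame_length = ", cfg$frame_length,
         " samples, got ", length(frame), call. = FALSE)
  }
  pg <- periodograms(matrix(frame, ncol = 1), cfg)
  structure(
    list(frequency = pg$freq, power = pg$power[, 1], dc = pg$dc[1],
         noise_floor = pg$noise_floor[1]),
    class = "ldf_spectrum"
  )
}

#' @export
print.ldf_spectrum <- function(x, ...) {
  cat("<ldf_spectrum>", length(x$frequency), "bins,",
      sprintf("dc %.4f V, noise floor %.3g V^2/Hz\n", x$dc, x$noise_floor))
  invisible(x)
}

band_rows <- function(freq, band) freq >= band[1] & freq <= band[2]

#' Velocity: first moment of the noise-subtracted power spectrum
#'
#' The noise floor is subtracted from the raw spectrum, negative residuals
#' are clipped to zero, and the power-weighted mean frequency is taken over
#' the analysis band. A spectrum with no residual in-band power yields 0 Hz
#' with attribute `valid = FALSE` rather than an error, so perfusion traces
#' stay aligned in time.
#'
#' @param spectrum An `ldf_spectrum`.
#' @param cfg An [acquisition_config()].
#' @return Velocity in Hz, with a logical attribute `valid`.
#' @export
compute_vel <- function(spectrum, cfg = acquisition_config()) {
  rows <- band_rows(spectrum$frequency, cfg$analysis_band)
  s <- pmax(spectrum$power[rows] - spectrum$noise_floor, 0)
  tot <- sum(s)
  if (tot <= 0) return(structure(0, valid = FALSE))
  structure(sum(spectrum$frequency[rows] * s) / tot, valid = TRUE)
}

#' Volume: DC-squared normalised integral of the power spectrum
#'
#' In-band noise-subtracted spectral power divided by DC squared; invariant
#' under global amplitude scaling of the signal and proportional to the
#' moving-scatterer concentration.
#'
#' @inheritParams compute_vel
#' @return Volume in arbitrary units.
#' @export
compute_vol <- function(spectrum, cfg = acquisition_config()) {
  if (spectrum$dc <= 0) {
    stop("non-physical record: frame DC must be positive, got ",
         spectrum$dc, call. = FALSE)
  }
  rows <- band_rows(spectrum$frequency, cfg$analysis_band)
  s <- pmax(spectrum$power[rows] - spectrum$noise_floor, 0)
  sum(s) * cfg$df / spectrum$dc^2
}

#' Frame quality flags
#'
#' `quality_ok`: the mean raw spectral power in the QC band (400-500 Hz)
#' exceeds the noise floor estimated above 4 kHz - i.e. the frame contains
#' genuine Doppler power. `dc_stable`: the frame's DC lies within
#' `dc_stability_tolerance` of the running median of the trailing DC history.
#'
#' @param spectrum An `ldf_spectrum`.
#' @param dc_history Numeric vector of recent DC values (trailing window,
#'   most recent last, including the current frame).
#' @param cfg An [acquisition_config()].
#' @return A named logical vector `c(quality_ok =, dc_stable =)`.
#' @export
assess_quality <- function(spectrum, dc_history, cfg = acquisition_config()) {
  stopifnot(length(dc_history) >= 1)
  qc_rows <- band_rows(spectrum$frequency, cfg$qc_band)
  quality_ok <- mean(spectrum$power[qc_rows]) > spectrum$noise_floor
  med <- stats::median(dc_history)
  dc_stable <- abs(spectrum$dc - med) <= cfg$dc_stability_tolerance * med
  c(quality_ok = quality_ok, dc_stable = dc_stable)
}

#' Process a raw record into a perfusion trace
#'
#' Runs the full signal path on an `ldf_record`: framing, windowed
#' periodogram, per-frame noise-floor estimation and subtraction, velocity
#' and volume moments, and quality flags, emitting one sample per frame
#' (14 samples/s at the default configuration).
#'
#' @param record An `ldf_record` (from [synthesize_record()],
#'   [apply_protocol()] or [read_record()]).
#' @param cfg An [acquisition_config()].
#' @return A tibble of class `ldf_trace` with columns `time` (s, frame start),
#'   `dc` (V), `vel` (Hz), `vol` (a.u.), `valid` (in-band power present),
#'   `quality_ok`, `dc_stable`. Attributes: `cfg`, `truth`, `segment_map`,
#'   `scene_kind`, `seed`.
#' @examples
#' tr <- process_record(synthesize_record(scene_artery(651), 2, 1))
#' head(tr)
#' @export
process_record <- function(record, cfg = acquisition_config()) {
  stopifnot(inherits(record, "ldf_record"))
  if (record$sampling_rate != cfg$sampling_rate) {
    stop("record sampling rate (", record$sampling_rate,
         " Hz) does not match the configuration (", cfg$sampling_rate,
         " Hz)", call. = FALSE)
  }
  frames <- frame_signal(record, cfg)
  pg <- periodograms(frames, cfg)
  nf <- ncol(frames)
  rows <- band_rows(pg$freq, cfg$analysis_band)
  s <- pmax(sweep(pg$power[rows, , drop = FALSE], 2L, pg$noise_floor), 0)
  tot <- colSums(s)
  vel <- ifelse(tot > 0, colSums(pg$freq[rows] * s) / tot, 0)
  if (any(pg$dc <= 0)) {
    stop("non-physical record: frame DC must be positive", call. = FALSE)
  }
  vol <- tot * cfg$df / pg$dc^2
  qc_rows <- band_rows(pg$freq, cfg$qc_band)
  quality_ok <- colMeans(pg$power[qc_rows, , drop = FALSE]) > pg$noise_floor
  dc_stable <- dc_stability_flags(pg$dc, cfg)
  out <- tibble::tibble(
    time = (seq_len(nf) - 1L) / cfg$spectra_per_second,
    dc = pg$dc, vel = vel, vol = vol,
    valid = tot > 0, quality_ok = quality_ok, dc_stable = dc_stable
  )
  attr(out, "cfg") <- cfg
  attr(out, "truth") <- record$truth
  attr(out, "segment_map") <- record$segment_map
  attr(out, "scene_kind") <- record$scene$kind
  attr(out, "seed") <- record$seed
  class(out) <- c("ldf_trace", class(out))
  out
}

# Trailing running-median DC stability: each frame is compared with the
# median DC over the preceding dc_history_window seconds (itself included).
dc_stability_flags <- function(dc, cfg) {
  win <- cfg$dc_history_window * cfg$spectra_per_second
  n <- length(dc)
  flags <- logical(n)
  for (i in seq_len(n)) {
    h <- dc[max(1L, i - win + 1L):i]
    med <- stats::median(h)
    flags[i] <- abs(dc[i] - med) <= cfg$dc_stability_tolerance * med
  }
  flags
}

#' Average a perfusion trace over tiling windows
#'
#' Tiles the trace with non-overlapping windows of `window` seconds and
#' summarises DC, Vel and Vol over the samples that pass quality control
#' (`valid & quality_ok`, plus `dc_stable` when `require_valid = TRUE`).
#' Windows without any valid sample are marked `missing`.
#'
#' @param trace An `ldf_trace` from [process_record()].
#' @param window Window length, s; must not exceed the trace duration.
#' @param require_valid Additionally require DC stability.
#' @return A tibble with one row per window: `window`, `t_start`, `t_end`,
#'   `n`, `n_valid`, `dc_mean`, `dc_sd`, `vel_mean`, `vel_sd`, `vol_mean`,
#'   `vol_sd`, `missing`.
#' @examples
#' tr <- process_record(synthesize_record(scene_artery(651), 4, 1))
#' average_trace(tr, window = 2)
#' @export
average_trace <- function(trace, window, require_valid = FALSE) {
  cfg <- attr(trace, "cfg") %||% acquisition_config()
  duration <- nrow(trace) / cfg$spectra_per_second
  if (window > duration + 1e-9) {
    stop("window (", window, " s) exceeds the trace duration (",
         duration, " s)", call. = FALSE)
  }
  trace |>
    dplyr::mutate(
      window = floor(.data$time / window) + 1L,
      keep = .data$valid & .data$quality_ok &
        (!require_valid | .data$dc_stable)
    ) |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(
      t_start = min(.data$time),
      t_end = max(.data$time) + 1 / cfg$spectra_per_second,
      n = dplyr::n(),
      n_valid = sum(.data$keep),
      dc_mean = mean(.data$dc[.data$keep]),
      dc_sd = stats::sd(.data$dc[.data$keep]),
      vel_mean = mean(.data$vel[.data$keep]),
      vel_sd = stats::sd(.data$vel[.data$keep]),
      vol_mean = mean(.data$vol[.data$keep]),
      vol_sd = stats::sd(.data$vol[.data$keep]),
      .groups = "drop"
    ) |>
    dplyr::mutate(missing = .data$n_valid == 0L)
}
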