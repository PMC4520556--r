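#' Acquisition and analysis configuration
#'
#' Constants of the instrument's digital signal path. The defaults realise the
#' design of the rodent ocular flowmeter: the photocurrent is digitised at
#' 14336 Hz and Fourier-analysed in non-overlapping 1024-sample frames, i.e.
#' exactly 14 spectra per second with a 14 Hz bin width. The Nyquist frequency
#' (7168 Hz) comfortably exceeds the 5 kHz maximum Doppler shift the analysis
#' band must cover.
#'
#' @param sampling_rate Sampling rate of the photodetector signal, Hz.
#' @param frame_length Samples per analysis frame; `sampling_rate /
#'   frame_length` must be a whole number of spectra per second.
#' @param analysis_band Numeric length-2, Hz. Band over which velocity (first
#'   spectral moment) and volume (normalised spectral power) are computed.
#'   The default `c(28, 5012)` spans spectral bins 2-358: bin 1 (14 Hz) is
#'   excluded as DC leakage, and 28 Hz is the nearest bin edge to the
#'   instrument's nominal 30 Hz cut-on.
#' @param noise_band_low_edge Hz. The noise floor is the mean raw spectral
#'   power over bins strictly above this frequency (default 4 kHz), where no
#'   physiological Doppler power is expected.
#' @param qc_band Numeric length-2, Hz. A frame passes the spectral quality
#'   criterion when its mean raw power in this band (default 400-500 Hz)
#'   exceeds the noise floor.
#' @param dc_stability_tolerance Fractional tolerance on DC drift: a sample is
#'   DC-stable when its DC is within this fraction of the running median of DC
#'   over the trailing `dc_history_window` seconds.
#' @param dc_history_window Seconds of trailing DC history for the running
#'   median (default 10 s).
#' @param window Analysis window applied to each frame before the periodogram:
#'   `"hann"` (default; limits leakage of strong low-frequency content into
#'   the quality-control band) or `"rectangular"`.
#'
#' @return An object of class `ldf_config`: a named list of validated
#'   constants plus derived quantities `spectra_per_second`, `df` (bin width,
#'   Hz) and `nyquist` (Hz).
#' @examples
#' cfg <- acquisition_config()
#' cfg$spectra_per_second # 14
#' cfg$df # 14 Hz
#' @export
acquisition_config <- function(sampling_rate = 14336,
                               frame_length = 1024,
                               analysis_band = c(28, 5012),
                               noise_band_low_edge = 4000,
                               qc_band = c(400, 500),
                               dc_stability_tolerance = 0.10,
                               dc_history_window = 10,
                               window = c("hann", "rectangular")) {
  window <- match.arg(window)
  stopifnot(
    is.numeric(sampling_rate), length(sampling_rate) == 1L, sampling_rate > 0,
    is.numeric(frame_length), length(frame_length) == 1L, frame_length >= 2,
    frame_length == round(frame_length),
    length(analysis_band) == 2L, analysis_band[1] >= 0,
    analysis_band[1] < analysis_band[2],
    length(qc_band) == 2L, qc_band[1] < qc_band[2],
    dc_stability_tolerance > 0, dc_history_window > 0
  )
  sps <- sampling_rate / frame_length
  if (abs(sps - round(sps)) > 1e-9) {
    stop("sampling_rate / frame_length must be an integer number of spectra per second, got ",
         sps, call. = FALSE)
  }
  nyquist <- sampling_rate / 2
  if (analysis_band[2] > nyquist || noise_band_low_edge >= nyquist) {
    stop("need analysis_band upper edge <= Nyquist and noise_band_low_edge ",
         "< Nyquist (", nyquist, " Hz)", call. = FALSE)
  }
  if (noise_band_low_edge < qc_band[2]) {
    stop("noise_band_low_edge must lie above the QC band", call. = FALSE)
  }
  structure(
    list(
      sampling_rate = sampling_rate,
      frame_length = as.integer(frame_length),
      spectra_per_second = round(sps),
      df = sampling_rate / frame_length,
      nyquist = nyquist,
      analysis_band = as.numeric(analysis_band),
      noise_band_low_edge = noise_band_low_edge,
      qc_band = as.numeric(qc_band),
      dc_stability_tolerance = dc_stability_tolerance,
      dc_history_window = dc_history_window,
      window = window
    ),
    class = "ldf_config"
  )
}

#' @export
print.ldf_config <- function(x, ...) {
  cat("<ldf_config>\n")
  cat(sprintf("  sampling rate    : %g Hz\n", x$sampling_rate))
  cat(sprintf("  frame length     : %d samples (%d spectra/s, bin width %g Hz)\n",
              x$frame_length, x$spectra_per_second, x$df))
  cat(sprintf("  analysis band    : %g-%g Hz\n", x$analysis_band[1], x$analysis_band[2]))
  cat(sprintf("  noise floor band : > %g Hz\n", x$noise_band_low_edge))
  cat(sprintf("  QC band          : %g-%g Hz\n", x$qc_band[1], x$qc_band[2]))
  cat(sprintf("  DC stability     : %.0f%% of trailing %g s median\n",
              100 * x$dc_stability_tolerance, x$dc_history_window))
  cat(sprintf("  window           : %s\n", x$window))
  invisible(x)
}

# Frame-spectrum bin centre frequencies (one-sided, excluding the DC bin).
bin_frequencies <- function(cfg) {
  seq_len(cfg$frame_length %/% 2) * cfg$df
}

# Deterministic child-seed derivation: folds a root seed and a sequence of
# indices through a Lehmer-style recurrence, keeping everything < 2^31 - 1 so
# intermediate products stay exact in doubles.
derive_seed <- function(root, ...) {
  idx <- c(...)
  s <- as.numeric(root) %% 2147483647
  for (i in idx) {
    s <- (s * 69069 + as.numeric(i) + 1) %% 2147483647
  }
  as.integer(s)
}
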