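#' Write / read a signal record (float32 WAV + JSON sidecar)
#'
#' A record is stored as a mono 32-bit IEEE-float WAV file holding the raw
#' photocurrent samples, with a JSON sidecar (`<path>.json` with the `.wav`
#' extension replaced) carrying everything WAV cannot: the scene parameters,
#' seed, ground truth and segment map. The RIFF reader/writer handles
#' exactly this variant (mono, float32) and is implemented here because it
#' is the package's canonical raw-signal format.
#'
#' @param record An `ldf_record`.
#' @param path Output `.wav` path; the sidecar is written next to it.
#' @return `write_record()` returns `path` invisibly. `read_record()`
#'   returns an `ldf_record`; when the sidecar is missing the record loads
#'   with a warning, `truth = NULL` and an unknown scene.
#' @examples
#' rec <- synthesize_record(scene_wheel(10), 1, seed = 1)
#' p <- tempfile(fileext = ".wav")
#' write_record(rec, p)
#' rec2 <- read_record(p)
#' max(abs(rec2$samples - rec$samples)) # float32 quantisation only
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ldf_record"))
  write_wav_float32(record$samples, record$sampling_rate, path)
  sidecar <- list(
    sampling_rate = record$sampling_rate,
    duration = record$duration,
    seed = record$seed,
    scene = unclass(record$scene),
    truth = record$truth,
    segment_map = record$segment_map,
    ldfsim_version = as.character(utils::packageVersion("ldfsim"))
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  wav <- read_wav_float32(path)
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) {
    warning("sidecar ", sc_path, " missing: record loaded without scene/",
            "ground truth", call. = FALSE)
    meta <- NULL
  } else {
    meta <- tryCatch(
      jsonlite::read_json(sc_path, simplifyVector = TRUE),
      error = function(e) stop("corrupted sidecar JSON at ", sc_path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (!is.null(meta$sampling_rate) &&
        abs(meta$sampling_rate - wav$sampling_rate) > 1e-6) {
      stop("sampling-rate mismatch: WAV header says ", wav$sampling_rate,
           " Hz but sidecar says ", meta$sampling_rate, " Hz", call. = FALSE)
    }
  }
  scene <- if (!is.null(meta$scene)) {
    structure(meta$scene, class = "ldf_scene")
  } else {
    structure(list(kind = "unknown"), class = "ldf_scene")
  }
  seg <- meta$segment_map
  if (!is.null(seg) && length(seg)) seg <- tibble::as_tibble(seg) else seg <- NULL
  structure(
    list(
      samples = wav$samples,
      sampling_rate = wav$sampling_rate,
      duration = length(wav$samples) / wav$sampling_rate,
      scene = scene,
      seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NA_integer_,
      truth = meta$truth,
      segment_map = seg
    ),
    class = "ldf_record"
  )
}

sidecar_path <- function(path) sub("\\.wav$", ".json", path, ignore.case = TRUE)

# Minimal RIFF/WAVE writer: mono, 32-bit IEEE float (format code 3), with
# the fact chunk required for non-PCM data.
write_wav_float32 <- function(samples, sampling_rate, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  data_bytes <- 4 * n
  # RIFF size: 4 (WAVE) + (8+16) fmt + (8+4) fact + (8+data) data
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(4 + 24 + 12 + 8 + data_bytes), con, size = 4,
           endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little") # IEEE float
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(sampling_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sampling_rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little") # block align
  writeBin(32L, con, size = 2, endian = "little") # bits per sample
  writeChar("fact", con, eos = NULL)
  writeBin(4L, con, size = 4, endian = "little")
  writeBin(as.integer(n), con, size = 4, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(samples, con, size = 4, endian = "little")
  invisible(path)
}

read_wav_float32 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop(path, " is not a RIFF/WAVE file", call. = FALSE)
  }
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      code <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
      if (code != 3 || channels != 1 || bits != 32) {
        stop(path, ": unsupported WAV variant (need mono 32-bit IEEE ",
             "float; got format code ", code, ", ", channels,
             " channel(s), ", bits, " bits)", call. = FALSE)
      }
      fmt <- list(rate = rate)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "numeric", size / 4, size = 4,
                         endian = "little")
      break
    } else {
      readBin(con, "raw", size + size %% 2) # skip unknown chunk (padded)
    }
  }
  if (is.null(fmt) || is.null(samples)) {
    stop(path, ": missing fmt or data chunk", call. = FALSE)
  }
  list(samples = samples, sampling_rate = fmt$rate)
}

#' Write / read a perfusion trace as CSV
#'
#' The CSV has the fixed column set `time, dc, vel, vol, valid, quality_ok,
#' dc_stable`; numbers are written at full precision so a round trip is an
#' identity. `write_trace()` can additionally emit a JSON summary of
#' quality-control counts and windowed means.
#'
#' @param trace An `ldf_trace`.
#' @param path Output `.csv` path.
#' @param summary_path Optional path for a JSON summary (per-record QC
#'   counts and the whole-trace mean DC/Vel/Vol over valid samples).
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   the trace tibble (class `ldf_trace`).
#' @export
write_trace <- function(trace, path, summary_path = NULL) {
  cols <- c("time", "dc", "vel", "vol", "valid", "quality_ok", "dc_stable")
  stopifnot(all(cols %in% names(trace)))
  readr::write_csv(trace[, cols], path)
  if (!is.null(summary_path)) {
    keep <- trace$valid & trace$quality_ok
    summary <- list(
      n_samples = nrow(trace),
      n_quality_ok = sum(trace$quality_ok),
      n_dc_stable = sum(trace$dc_stable),
      n_invalid = sum(!trace$valid),
      dc_mean = mean(trace$dc[keep]),
      vel_mean = mean(trace$vel[keep]),
      vol_mean = mean(trace$vol[keep]),
      truth = attr(trace, "truth"),
      scene_kind = attr(trace, "scene_kind"),
      seed = attr(trace, "seed")
    )
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- readr::read_csv(
    path,
    col_types = readr::cols(
      time = readr::col_double(), dc = readr::col_double(),
      vel = readr::col_double(), vol = readr::col_double(),
      valid = readr::col_logical(), quality_ok = readr::col_logical(),
      dc_stable = readr::col_logical()
    )
  )
  probs <- readr::problems(tr)
  if (nrow(probs) > 0) {
    stop("malformed trace CSV ", path, ": first problem at line ",
         probs$row[1] + 1, " (", probs$expected[1], ")", call. = FALSE)
  }
  class(tr) <- c("ldf_trace", class(tr))
  tr
}
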