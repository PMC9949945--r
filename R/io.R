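#' Construct an audio recording
#'
#' Container for a single-channel respiratory sound signal: dimensionless
#' amplitudes, a sampling rate in Hz and the time offset of the first sample.
#'
#' @param samples numeric vector of amplitudes.
#' @param rate sampling rate in samples/second; must be positive.
#' @param t0 time of the first sample in seconds (default 0).
#' @return An object of class `audio_recording` with fields `samples`,
#'   `rate` and `t0`.
#' @export
audio_recording <- function(samples, rate, t0 = 0) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("samples must be a non-empty numeric vector")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate),
                 t0 = as.numeric(t0)),
            class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, x$t0))
  invisible(x)
}

#' Construct a 1 Hz SpO2 trace
#'
#' @param values percent oxygen saturation, each in \[0, 100\].
#' @param t0 time of the first sample in seconds.
#' @return An object of class `spo2_trace` with fields `values`, `rate`
#'   (fixed at 1 Hz) and `t0`.
#' @export
spo2_trace <- function(values, t0 = 0) {
  if (!is.numeric(values) || length(values) == 0L)
    stop("values must be a non-empty numeric vector")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 100))
    stop("SpO2 values must be finite and within [0, 100]")
  structure(list(values = as.numeric(values), rate = 1, t0 = as.numeric(t0)),
            class = "spo2_trace")
}

#' @export
print.spo2_trace <- function(x, ...) {
  cat(sprintf("<spo2_trace> %d s @ 1 Hz, range [%.1f, %.1f]%%\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# --- WAV (RIFF/WAVE) ---------------------------------------------------------
# No audio package ships with the target environment, so a minimal RIFF
# reader/writer lives here. Supports PCM 8/16/24/32-bit and IEEE float 32/64,
# mono or multichannel (only channel 1 is kept: the recorder is a single
# tracheal microphone).

#' Read a WAV file as a mono recording
#'
#' Multichannel files are collapsed to the first channel. Integer PCM samples
#' are rescaled to \[-1, 1\].
#'
#' @param path path to a RIFF/WAVE file.
#' @return An [audio_recording()] with the header's sampling rate.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        code     = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate     = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)
  if (fmt$code == 65534L) fmt$code <- 1L  # WAVE_FORMAT_EXTENSIBLE: assume PCM layout

  bytes <- fmt$bits %/% 8L
  n_tot <- length(data_raw) %/% bytes
  x <- if (fmt$code == 1L) {
    if (fmt$bits == 8L) {
      (as.numeric(readBin(data_raw, "integer", n_tot, 1, signed = FALSE)) - 128) / 128
    } else if (fmt$bits == 16L) {
      readBin(data_raw, "integer", n_tot, 2, signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 24L) {
      m <- matrix(as.integer(data_raw), nrow = 3L)
      v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 32L) {
      readBin(data_raw, "integer", n_tot, 4, endian = "little") / 2147483648
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else if (fmt$code == 3L) {
    readBin(data_raw, "numeric", n_tot, size = bytes, endian = "little")
  } else stop("unsupported WAV format code: ", fmt$code)

  if (fmt$channels > 1L) {
    n_frames <- length(x) %/% fmt$channels
    x <- x[seq(1L, by = fmt$channels, length.out = n_frames)]
  }
  audio_recording(x, fmt$rate)
}

#' Write a mono recording as WAV
#'
#' @param rec an [audio_recording()] or numeric vector.
#' @param path output path.
#' @param rate sampling rate, required when `rec` is a bare vector.
#' @param bit_depth `16` (PCM, default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, rate = NULL, bit_depth = 16L) {
  if (is.numeric(rec)) rec <- audio_recording(rec, rate)
  x <- pmin(1, pmax(-1, rec$samples))
  con <- file(path, "wb")
  on.exit(close(con))
  float <- identical(bit_depth, "float32")
  bytes <- if (float) 4L else 2L
  n <- length(x)
  data_sz <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (float) 3L else 1L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                      # mono
  writeBin(as.integer(round(rec$rate)), con, 4, endian = "little")
  writeBin(as.integer(round(rec$rate)) * bytes, con, 4, endian = "little")
  writeBin(bytes, con, 2, endian = "little")
  writeBin(8L * bytes, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (float) {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    q <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

# --- SpO2 / results CSV ------------------------------------------------------

#' Read a 1 Hz SpO2 series from CSV
#'
#' Expects columns `time_s` (consecutive integer seconds) and `spo2_percent`.
#'
#' @param path CSV path.
#' @return An [spo2_trace()] with `t0` equal to the first timestamp.
#' @export
read_spo2_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "spo2_percent") %in% names(df)))
    stop("SpO2 CSV must have columns time_s,spo2_percent")
  t <- df$time_s
  if (any(diff(t) != 1) || any(t != round(t)))
    stop("time_s must be consecutive integer seconds")
  spo2_trace(df$spo2_percent, t0 = t[1])
}

#' Write an SpO2 trace to CSV
#' @param trace an [spo2_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spo2_csv <- function(trace, path) {
  stopifnot(inherits(trace, "spo2_trace"))
  df <- data.frame(time_s = trace$t0 + seq_along(trace$values) - 1,
                   spo2_percent = trace$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-clip results table to CSV
#'
#' Header: `clip_index,label,mbpi_s,elapsed_min,pred_level,loo2,ref_level`.
#'
#' @param results data.frame with those columns (extra columns dropped).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  cols <- c("clip_index", "label", "mbpi_s", "elapsed_min",
            "pred_level", "loo2", "ref_level")
  for (cl in setdiff(cols, names(results))) results[[cl]] <- NA
  utils::write.csv(results[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
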