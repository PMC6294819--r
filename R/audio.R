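#' Audio signal container
#'
#' A sampled mono waveform. Amplitudes are dimensionless with nominal range
#' [-1, 1]; the sampling rate is in Hz.
#'
#' @param samples numeric vector of finite amplitudes.
#' @param rate sampling rate in Hz (> 0).
#' @return An object of class `audio_signal` with elements `samples`, `rate`
#'   and `duration` (seconds).
#' @examples
#' s <- audio_signal(sin(2 * pi * 100 * seq(0, 1, by = 1/8000)), 8000)
#' s$duration
#' @export
audio_signal <- function(samples, rate) {
  stopifnot_scalar(rate, "rate")
  if (rate <= 0) stop("'rate' must be positive", call. = FALSE)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty signal", call. = FALSE)
  if (!all(is.finite(samples))) stop("signal contains non-finite samples", call. = FALSE)
  structure(list(samples = samples, rate = rate,
                 duration = length(samples) / rate),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s), range [%.3f, %.3f]\n",
              length(x$samples), x$rate, x$duration,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE files containing integer PCM (8/16/24/32-bit) or IEEE
#' float (32/64-bit) data. Multichannel input is downmixed to mono by
#' averaging channels. Amplitudes are normalised to [-1, 1].
#'
#' @param path path to a `.wav` file.
#' @return An [audio_signal].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        rate     = readBin(con, "integer", 1, 4, endian = "little"),
        byterate = readBin(con, "integer", 1, 4, endian = "little"),
        align    = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits     = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
      next
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("missing fmt/data chunk in ", path, call. = FALSE)

  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- if (fmt$format == 3L) {           # IEEE float
    readBin(data_raw, "double", n, size = bytes, endian = "little")
  } else if (fmt$bits == 8L) {           # unsigned
    (readBin(data_raw, "integer", n, 1, signed = FALSE) - 128) / 128
  } else if (fmt$bits == 16L) {
    readBin(data_raw, "integer", n, 2, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    b <- as.integer(data_raw)
    i <- seq(1L, 3L * (n %/% 1L), by = 3L)
    v <- b[i] + 256 * b[i + 1L] + 65536 * b[i + 2L]
    (ifelse(v >= 8388608, v - 16777216, v)) / 8388608
  } else if (fmt$bits == 32L) {
    readBin(data_raw, "integer", n, 4, endian = "little") / 2147483648
  } else stop("unsupported bit depth: ", fmt$bits, call. = FALSE)

  if (fmt$channels > 1L) {
    m <- matrix(x[seq_len((length(x) %/% fmt$channels) * fmt$channels)],
                nrow = fmt$channels)
    x <- colMeans(m)
  }
  audio_signal(x, fmt$rate)
}

#' Write a PCM WAV file
#'
#' Writes 16-bit integer PCM, the protocol's recording format. Samples are
#' clipped to [-1, 1] before quantisation.
#'
#' @param signal an [audio_signal].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- pmin(1, pmax(-1, signal$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, size = 2, endian = "little")       # PCM, mono
  writeBin(as.integer(signal$rate), con, size = 4, endian = "little")
  writeBin(as.integer(signal$rate * 2), con, size = 4, endian = "little")
  writeBin(as.integer(c(2, 16)), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# Resample by linear interpolation onto the new rate's sample grid. Adequate
# here because it is only used to bring the band of interest below Nyquist for
# formant analysis (a low-pass via decimation path) and for synthesis helpers.
resample_signal <- function(signal, new_rate) {
  if (abs(new_rate - signal$rate) < 1e-9) return(signal)
  n_new <- max(2L, floor(signal$duration * new_rate))
  t_new <- (seq_len(n_new) - 1) / new_rate
  t_old <- (seq_along(signal$samples) - 1) / signal$rate
  if (new_rate < signal$rate) {
    # anti-alias low-pass before decimation
    nyq <- new_rate / 2
    bf <- signal::butter(6, nyq / (signal$rate / 2) * 0.95)
    y <- signal::filtfilt(bf, signal$samples)
  } else y <- signal$samples
  audio_signal(stats::approx(t_old, y, xout = t_new, rule = 2)$y, new_rate)
}
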