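#' Mono audio signal
#'
#' Container for a sampled mono waveform. Samples are dimensionless
#' amplitudes, nominally in \code{[-1, 1]}; \code{rate} is the sampling
#' frequency in Hz.
#'
#' @param samples Numeric vector of finite sample values.
#' @param rate Sampling rate in Hz (> 0).
#' @return An object of class \code{audio_signal} with fields
#'   \code{samples} and \code{rate}.
#' @export
audio_signal <- function(samples, rate) {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), peak %.3f>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param signal An \code{audio_signal}.
#' @return Duration in seconds.
#' @export
duration <- function(signal) length(signal$samples) / signal$rate

# ---- WAV (RIFF) I/O -------------------------------------------------------
# Minimal RIFF/WAVE codec for the two dialects used here: mono PCM16 and
# mono IEEE float32. No audio package is available in the target library,
# so the container is read/written directly.

#' Read a mono WAV file
#'
#' Supports the RIFF/WAVE container with 16-bit PCM or 32-bit IEEE float
#' samples, one channel. PCM samples are scaled to \code{[-1, 1]} by
#' division by 32768.
#'
#' @param path Path to a WAV file.
#' @return An \code{audio_signal}.
#' @export
load_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format    = readBin(con, "integer", 1, size = 2, endian = "little"),
        channels  = readBin(con, "integer", 1, size = 2, endian = "little"),
        rate      = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        align     = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits      = readBin(con, "integer", 1, size = 2, endian = "little"))
      extra <- sz - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV file: ", path)
  if (fmt$channels != 1L)
    stop("multi-channel WAV not supported (", fmt$channels, " channels)")

  if (fmt$format == 1L && fmt$bits == 16L) {
    n <- length(data_raw) %/% 2L
    s <- readBin(data_raw, "integer", n, size = 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    n <- length(data_raw) %/% 4L
    s <- readBin(data_raw, "numeric", n, size = 4, endian = "little")
  } else {
    stop("unsupported WAV encoding: format tag ", fmt$format, ", ",
         fmt$bits, " bits (expected PCM16 or float32)")
  }
  audio_signal(s, fmt$rate)
}

#' Write a mono WAV file
#'
#' Samples outside \code{[-1, 1]} are clipped, with a warning. PCM16
#' quantization divides the unit range into 32768 steps.
#'
#' @param signal An \code{audio_signal}.
#' @param path Output path.
#' @param format \code{"pcm16"} (default) or \code{"float32"}.
#' @return \code{path}, invisibly.
#' @export
save_wav <- function(signal, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  stopifnot(inherits(signal, "audio_signal"))
  s <- signal$samples
  if (any(s > 1 | s < -1)) {
    warning("samples outside [-1, 1] clipped on write")
    s <- pmin(1, pmax(-1, s))
  }
  n <- length(s)
  bytes_per <- if (format == "pcm16") 2L else 4L
  data_size <- n * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, size = 2,
           endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # channels
  writeBin(as.integer(round(signal$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(signal$rate) * bytes_per), con, size = 4,
           endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")       # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(pmin(32767, pmax(-32768, round(s * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(s, con, size = 4, endian = "little")
  }
  invisible(path)
}
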