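#' Analysis window
#'
#' A symmetric, nonnegative tapering window of even length used for STFT
#' analysis and synthesis. The periodic Hann window is the default
#' throughout the package.
#'
#' @param values Numeric vector of window samples.
#' @return An object of class \code{analysis_window}.
#' @export
analysis_window <- function(values) {
  n <- length(values)
  if (n < 4L || n %% 2L != 0L) stop("window length must be even and >= 4")
  if (any(values < 0)) stop("window must be nonnegative")
  # symmetry in the periodic convention: h[k] == h[N-k]
  if (n > 2L && max(abs(values[-1L] - rev(values[-1L]))) > 1e-9 &&
      max(abs(values - rev(values))) > 1e-9)
    stop("window must be symmetric")
  structure(list(values = as.numeric(values), size = n),
            class = "analysis_window")
}

#' Periodic Hann window
#' @param n Even window length in samples.
#' @return An \code{analysis_window}.
#' @export
hann_window <- function(n) {
  analysis_window(0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n))
}

#' Rectangular window
#' @param n Even window length in samples.
#' @return An \code{analysis_window}.
#' @export
rect_window <- function(n) analysis_window(rep(1, n))

# Default window size: ~46 ms, rounded to the nearest power of two
# (2048 samples at 44.1 kHz).
default_window_size <- function(rate) {
  2L^max(5L, round(log2(0.0464 * rate)))
}

reflect_pad <- function(x, pad) {
  n <- length(x)
  if (pad >= n) stop("window longer than signal; cannot pad")
  c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
}

#' Short-term Fourier transform
#'
#' Cuts the signal into frames of length \code{N = length(window)} taken
#' every \code{analysis_hop} samples, multiplies each frame by the window
#' and takes its (unnormalized) DFT. With \code{pad = TRUE} (default) the
#' signal is reflect-padded by \code{N/2} on both ends so that frame
#' \code{u} is centered on input sample \code{analysis_hop * u} and every
#' frame is fully defined.
#'
#' @param signal An \code{audio_signal}.
#' @param window An \code{analysis_window} (default: Hann, ~46 ms).
#' @param analysis_hop Hop size in samples (default \code{N/4}).
#' @param pad Center frames by reflect-padding (default \code{TRUE}).
#' @return A \code{spectrogram}: complex coefficient grid (bins x frames)
#'   plus window, hop and rate metadata.
#' @export
stft <- function(signal, window = NULL, analysis_hop = NULL, pad = TRUE) {
  stopifnot(inherits(signal, "audio_signal"))
  if (is.null(window)) window <- hann_window(default_window_size(signal$rate))
  N <- window$size
  if (is.null(analysis_hop)) analysis_hop <- N %/% 4L
  if (analysis_hop < 1L) stop("analysis_hop must be >= 1")
  L <- length(signal$samples)
  if (pad) {
    centers <- seq(0L, by = as.integer(analysis_hop),
                   length.out = L %/% analysis_hop + 1L)
  } else {
    if (L < N) stop("window longer than signal")
    centers <- seq(0L, by = as.integer(analysis_hop),
                   length.out = (L - N) %/% analysis_hop + 1L) + N %/% 2L
  }
  spec <- stft_at(signal, window, centers, pad = pad)
  spec$analysis_hop <- as.integer(analysis_hop)
  spec
}

# STFT with frames centered at arbitrary sample positions (0-based).
# Used by the variable-hop time stretch.
stft_at <- function(signal, window, centers, pad = TRUE) {
  N <- window$size
  half <- N %/% 2L
  x <- signal$samples
  L <- length(x)
  if (pad) {
    xp <- reflect_pad(x, half)
    starts <- as.integer(round(centers))            # padded index of n = 0
  } else {
    xp <- x
    starts <- as.integer(round(centers)) - half
    if (any(starts < 0L) || any(starts + N > L))
      stop("frame exceeds signal; use pad = TRUE")
  }
  idx <- outer(seq_len(N), starts, `+`)             # N x U, 1-based
  frames <- matrix(xp[idx], nrow = N)
  coeffs <- stats::mvfft(frames * window$values)
  structure(list(coeffs = coeffs, window = window, rate = signal$rate,
                 analysis_hop = NA_integer_, synthesis_hop = NA_integer_,
                 frame_pos = as.numeric(round(centers)), pad = pad,
                 orig_length = L),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram: %d bins x %d frames, N=%d, Ra=%s, Rs=%s, %g Hz>\n",
    nrow(x$coeffs), ncol(x$coeffs), x$window$size,
    ifelse(is.na(x$analysis_hop), "var", x$analysis_hop),
    ifelse(is.na(x$synthesis_hop), "unset", x$synthesis_hop), x$rate))
  invisible(x)
}

n_frames <- function(spec) ncol(spec$coeffs)
n_bins <- function(spec) nrow(spec$coeffs)

#' Inverse short-term Fourier transform
#'
#' Per-frame inverse DFT (carrying the \code{1/N} factor), windowing, and
#' overlap-add at multiples of the synthesis hop. The result is normalized
#' by the overlap-added squared window, so reconstruction is exact for any
#' window/hop whose squared overlap-add stays strictly positive.
#'
#' @param spec A \code{spectrogram} with \code{synthesis_hop} set (defaults
#'   to the analysis hop when unset).
#' @param expected_length Output length in samples; defaults to the input
#'   length scaled by \code{synthesis_hop / analysis_hop}.
#' @return An \code{audio_signal}.
#' @export
istft <- function(spec, expected_length = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  Rs <- spec$synthesis_hop
  if (is.na(Rs) || is.null(Rs)) Rs <- spec$analysis_hop
  if (is.na(Rs)) stop("synthesis_hop not set")
  Rs <- as.integer(Rs)
  N <- spec$window$size
  h <- spec$window$values
  U <- n_frames(spec)
  half <- N %/% 2L

  frames <- Re(stats::mvfft(spec$coeffs, inverse = TRUE)) / N
  frames <- frames * h

  buf_len <- Rs * (U - 1L) + N
  y <- numeric(buf_len)
  wsum <- numeric(buf_len)
  h2 <- h * h
  for (u in seq_len(U)) {
    at <- (u - 1L) * Rs + seq_len(N)
    y[at] <- y[at] + frames[, u]
    wsum[at] <- wsum[at] + h2
  }

  if (is.null(expected_length)) {
    ra <- spec$analysis_hop
    expected_length <-
      if (!is.na(ra)) as.integer(round(spec$orig_length * Rs / ra))
      else buf_len - N
  }
  # region of interest on the synthesis timeline
  if (spec$pad) roi <- half + seq_len(expected_length)
  else roi <- seq_len(min(expected_length, buf_len))
  roi <- roi[roi <= buf_len]
  if (any(wsum[roi] < 1e-10 * max(wsum)))
    stop("overlap-add gain hits zero: hop incompatible with window")
  out <- y[roi] / wsum[roi]
  if (length(out) < expected_length)
    out <- c(out, numeric(expected_length - length(out)))
  audio_signal(out, spec$rate)
}
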