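#' Autocorrelation pitch tracking
#'
#' Frame-wise fundamental-frequency estimation by the normalized
#' autocorrelation method. A frame is voiced when its strongest
#' autocorrelation peak in the candidate lag range exceeds
#' \code{voicing_threshold} and the frame carries appreciable energy; the
#' lag of that peak is refined by parabolic interpolation. This simple
#' tracker is intended for clean, synthetic or near-periodic material
#' (the pitch-flattening workflow), not as a production f0 tracker.
#'
#' @param signal An \code{audio_signal} (voiced, periodic content).
#' @param frame_step Analysis step in seconds (default 0.01).
#' @param f0_range Candidate range in Hz (default \code{c(60, 500)}).
#' @param frame_length Analysis frame in seconds (default: two periods of
#'   the range minimum, at least 0.03).
#' @param voicing_threshold Normalized autocorrelation threshold (0.5).
#' @return Data frame with columns \code{time} (frame center, s) and
#'   \code{f0} (Hz), voiced frames only. Errors if no frame is voiced.
#' @export
estimate_pitch_contour <- function(signal, frame_step = 0.01,
                                   f0_range = c(60, 500),
                                   frame_length = NULL,
                                   voicing_threshold = 0.5) {
  stopifnot(inherits(signal, "audio_signal"))
  rate <- signal$rate
  if (is.null(frame_length))
    frame_length <- max(0.03, 2 / f0_range[1L])
  flen <- as.integer(round(frame_length * rate))
  step <- max(1L, as.integer(round(frame_step * rate)))
  x <- signal$samples
  L <- length(x)
  if (L < flen) stop("signal shorter than one analysis frame")

  lag_min <- max(2L, as.integer(floor(rate / f0_range[2L])))
  lag_max <- min(flen - 2L, as.integer(ceiling(rate / f0_range[1L])))
  if (lag_max <= lag_min) stop("f0 range incompatible with frame length")

  starts <- seq(1L, L - flen + 1L, by = step)
  nfft <- 2L^ceiling(log2(2L * flen))
  rms_all <- sqrt(mean(x^2))

  times <- f0s <- numeric(0)
  for (s in starts) {
    fr <- x[s:(s + flen - 1L)]
    fr <- fr - mean(fr)
    if (sqrt(mean(fr^2)) < max(1e-6, 0.05 * rms_all)) next
    sp <- stats::fft(c(fr, numeric(nfft - flen)))
    ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE)) / nfft
    # biased normalized autocorrelation: the (flen - lag)/flen taper
    # penalizes octave-down candidates at multiples of the true period
    lags <- lag_min:lag_max
    r <- ac[lags + 1L] / ac[1L]
    i <- which.max(r)
    if (r[i] < voicing_threshold) next
    # parabolic refinement of the peak lag
    lag <- lags[i]
    if (i > 1L && i < length(r)) {
      a <- r[i - 1L]; b <- r[i]; c2 <- r[i + 1L]
      den <- a - 2 * b + c2
      if (abs(den) > 1e-12) lag <- lag + 0.5 * (a - c2) / den
    }
    times <- c(times, (s - 1L + flen / 2) / rate)
    f0s <- c(f0s, rate / lag)
  }
  if (length(f0s) == 0L)
    stop("no voiced frames found (signal may be unvoiced noise)")
  data.frame(time = times, f0 = f0s)
}
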