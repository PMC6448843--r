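#' Phase-locked phase propagation
#'
#' Adapts STFT phases when frames are re-positioned in time (vertical
#' phase synchronization). Per frame, prominent amplitude peaks are found
#' along the frequency axis; phases are extrapolated only at peak bins —
#' the phase advance observed between consecutive analysis frames
#' (principal-value unwrapped against the bin frequency) is rescaled by
#' the hop ratio and accumulated — while every other bin inside a peak's
#' region of influence receives the same phase rotation as its peak, which
#' preserves the relative phase structure that carries timbre.
#'
#' @param spec A \code{spectrogram} (real-signal STFT).
#' @param per_frame_hop_ratio Ratio \code{Rs/Ra} per frame (scalar
#'   recycled). Ratio 1 leaves phases untouched (modulo 2 pi).
#' @return A \code{spectrogram} with modified phases and
#'   \code{synthesis_hop} set.
#' @export
propagate_phases <- function(spec, per_frame_hop_ratio) {
  stopifnot(inherits(spec, "spectrogram"))
  U <- n_frames(spec)
  if (U == 0L) stop("empty spectrogram")
  ratios <- rep_len(as.numeric(per_frame_hop_ratio), U)
  if (any(ratios <= 0)) stop("hop ratios must be strictly positive")
  N <- n_bins(spec)
  K <- N %/% 2L + 1L                     # nonnegative-frequency bins
  pos <- spec$frame_pos
  ra <- if (U > 1L) diff(pos) else numeric(0)
  if (any(ra <= 0)) stop("frame positions must be strictly increasing")

  X <- spec$coeffs[seq_len(K), , drop = FALSE]
  mag <- Mod(X)
  phi_in <- Arg(X)
  phi_out <- phi_in
  omega <- 2 * pi * (0:(K - 1L)) / N

  for (u in 2:max(2L, U)) {
    if (U < 2L) break
    Ra <- ra[u - 1L]
    peaks <- find_peaks(mag[, u])
    if (length(peaks) == 0L) { phi_out[, u] <- phi_in[, u]; next }
    dphi <- phi_in[peaks, u] - phi_in[peaks, u - 1L] - omega[peaks] * Ra
    dphi <- princarg(dphi)
    advance <- (omega[peaks] * Ra + dphi) * ratios[u]
    new_peak_phase <- phi_out[peaks, u - 1L] + advance
    rot <- new_peak_phase - phi_in[peaks, u]
    # region of influence: midpoints between adjacent peaks
    if (length(peaks) > 1L) {
      bounds <- (peaks[-1L] + peaks[-length(peaks)]) / 2
      region <- findInterval(seq_len(K), bounds) + 1L
    } else region <- rep(1L, K)
    phi_out[, u] <- phi_in[, u] + rot[region]
  }

  Y <- complex(modulus = as.vector(mag), argument = as.vector(phi_out))
  Y <- matrix(Y, nrow = K)
  out <- spec
  out$coeffs <- hermitian_expand(Y, N)
  rs <- stats::median(if (U > 1L) ra * ratios[-1L] else
                        spec$analysis_hop * ratios)
  out$synthesis_hop <- as.integer(round(rs))
  out
}

# strict local maxima over the 2 nearest neighbors on each side
find_peaks <- function(m) {
  K <- length(m)
  if (K < 5L) return(if (K) which.max(m) else integer(0))
  mm <- c(-Inf, -Inf, m, -Inf, -Inf)
  i <- 3:(K + 2L)
  hits <- mm[i] > mm[i - 1L] & mm[i] > mm[i - 2L] &
          mm[i] > mm[i + 1L] & mm[i] > mm[i + 2L]
  peaks <- which(hits)
  tol <- 1e-12 * max(m)
  peaks[m[peaks] > tol]
}

princarg <- function(phi) phi - 2 * pi * round(phi / (2 * pi))

# rebuild the full N-bin spectrum of a real signal from bins 0..N/2;
# bins 0 and N/2 must stay real, so a rotated phase collapses to its sign
hermitian_expand <- function(Yhalf, N) {
  K <- nrow(Yhalf)                       # N/2 + 1
  full <- rbind(Yhalf, Conj(Yhalf[(K - 1L):2L, , drop = FALSE]))
  full[1L, ] <- as.complex(Mod(Yhalf[1L, ]) * cos_sign(Arg(Yhalf[1L, ])))
  full[K, ] <- as.complex(Mod(Yhalf[K, ]) * cos_sign(Arg(Yhalf[K, ])))
  stopifnot(nrow(full) == N)
  full
}

cos_sign <- function(phi) ifelse(cos(phi) >= 0, 1, -1)

# Evaluate a BPF as a stretch-factor function of input time (seconds).
as_t_fun <- function(bpf) function(tt) evaluate_bpf(bpf, tt)

# Core variable-hop vocoder stretch. t_fun maps input time (s) to a
# stretch factor > 0. Returns the stretched audio_signal.
vocoder_stretch <- function(signal, t_fun, window = NULL) {
  rate <- signal$rate
  if (is.null(window)) window <- hann_window(default_window_size(rate))
  N <- window$size
  Rs <- N %/% 4L
  L <- length(signal$samples)

  # per-sample stretch factors; output length is the integral of t
  tt <- t_fun((seq_len(L) - 1L) / rate)
  if (any(!is.finite(tt)) || any(tt <= 0))
    stop("stretch factors must be finite and > 0")
  out_len <- as.integer(round(sum(tt)))

  # analysis frame centers: advance Rs / t per output hop
  pos <- 0
  centers <- numeric(0)
  while (pos < L) {
    centers <- c(centers, pos)
    step <- Rs / t_fun(pos / rate)
    pos <- pos + max(1, step)
  }
  if (length(centers) < 2L) centers <- c(0, L)
  centers <- round(centers)
  centers <- centers[!duplicated(centers)]

  spec <- stft_at(signal, window, centers)
  ratios <- c(1, Rs / diff(centers))
  spec <- propagate_phases(spec, ratios)
  spec$synthesis_hop <- Rs
  istft(spec, expected_length = out_len)
}

#' Time-varying time stretch
#'
#' Stretches or compresses local duration according to a breakpoint
#' function of stretch factors \code{t} (\code{t = 1} no change,
#' \code{t > 1} slower) defined on the input timeline, while leaving pitch
#' and amplitude unchanged. Realized with a phase-locked vocoder whose
#' analysis hop varies as \code{Rs / t} against a constant synthesis hop.
#'
#' @param signal An \code{audio_signal}.
#' @param bpf A \code{bpf} with dimension \code{"stretch"}, or a single
#'   number for a static stretch.
#' @param window Optional \code{analysis_window}.
#' @return The stretched \code{audio_signal}; its duration approximates
#'   the integral of \code{t} over the input duration.
#' @export
time_stretch <- function(signal, bpf, window = NULL) {
  stopifnot(inherits(signal, "audio_signal"))
  if (is.numeric(bpf) && length(bpf) == 1L)
    bpf <- bpf_static(bpf, "stretch")
  if (any(bpf$values <= 0)) stop("stretch factors must be > 0")
  vocoder_stretch(signal, as_t_fun(bpf), window)
}

#' Time-varying pitch shift
#'
#' Shifts pitch according to a breakpoint function in cents (0 = no
#' change; +1200 = one octave up) while preserving duration and amplitude.
#' Implemented as a vocoder time stretch by the local ratio
#' \code{p = 2^(cents/1200)} followed by time-varying resampling by
#' \code{1/p}, which restores every local duration exactly (output time
#' equals input time by construction).
#'
#' @param signal An \code{audio_signal}.
#' @param bpf A \code{bpf} with dimension \code{"pitch"} (values in
#'   cents), or a single number of cents.
#' @param window Optional \code{analysis_window}.
#' @return An \code{audio_signal} of (near-)identical duration.
#' @export
pitch_shift <- function(signal, bpf, window = NULL) {
  stopifnot(inherits(signal, "audio_signal"))
  if (is.numeric(bpf) && length(bpf) == 1L)
    bpf <- bpf_static(bpf, "pitch")
  if (any(!is.finite(bpf$values))) stop("pitch shift cents must be finite")
  rate <- signal$rate
  p_fun <- function(tt) 2^(evaluate_bpf(bpf, tt) / 1200)

  stretched <- vocoder_stretch(signal, p_fun, window)
  # output sample m sits at input time m; its read position in the
  # stretched signal is the accumulated stretch integral up to m
  L <- length(signal$samples)
  p <- p_fun((seq_len(L) - 1L) / rate)
  read_pos <- cumsum(p)                          # in stretched samples
  read_pos <- pmin(read_pos, length(stretched$samples))
  y <- stats::approx(seq_along(stretched$samples), stretched$samples,
                     xout = pmax(1, read_pos), rule = 2)$y
  audio_signal(y, rate)
}

#' Time-varying amplitude (gain) transformation
#'
#' Applies a breakpoint function of gains in dB as a time-frequency mask:
#' STFT amplitudes of frame \code{u} are multiplied by
#' \code{10^(g(tau_u)/20)}, phases are left unchanged, and the signal is
#' resynthesized. Pitch and duration are unaffected.
#'
#' @param signal An \code{audio_signal}.
#' @param bpf A \code{bpf} with dimension \code{"gain"} (values in dB), or
#'   a single number of dB.
#' @param window Optional \code{analysis_window}.
#' @return An \code{audio_signal}.
#' @export
apply_gain <- function(signal, bpf, window = NULL) {
  stopifnot(inherits(signal, "audio_signal"))
  if (is.numeric(bpf) && length(bpf) == 1L)
    bpf <- bpf_static(bpf, "gain")
  spec <- stft(signal, window)
  g_db <- evaluate_bpf(bpf, spec$frame_pos / signal$rate)
  gains <- 10^(g_db / 20)
  spec$coeffs <- sweep(spec$coeffs, 2L, gains, `*`)
  spec$synthesis_hop <- spec$analysis_hop
  istft(spec, expected_length = length(signal$samples))
}

#' Resample a signal by a length ratio
#'
#' Band-limited (Fourier) resampling: the output has
#' \code{round(n * ratio)} samples at the same nominal rate, so all
#' frequencies are scaled by \code{1/ratio}.
#'
#' @param signal An \code{audio_signal}.
#' @param ratio Positive length ratio (\code{0.5} halves the duration and
#'   doubles every frequency).
#' @return An \code{audio_signal}.
#' @export
resample <- function(signal, ratio) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
      ratio <= 0)
    stop("ratio must be a single positive number")
  x <- signal$samples
  n <- length(x)
  m <- max(1L, as.integer(round(n * ratio)))
  if (m == n) return(signal)
  X <- stats::fft(x)
  half <- min(n, m) %/% 2L
  Y <- complex(real = numeric(m), imaginary = numeric(m))
  Y[1:(half + 1L)] <- X[1:(half + 1L)]
  if (half > 1L) Y[m - (1:(half - 1L)) + 1L] <- X[n - (1:(half - 1L)) + 1L]
  if (min(n, m) %% 2L == 0L) {
    # split the shared Nyquist bin to keep the signal real
    ny <- X[half + 1L]
    if (m > n) { Y[half + 1L] <- ny / 2; Y[m - half + 1L] <- Conj(ny) / 2 }
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  audio_signal(y, signal$rate)
}
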