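#' Synthetic test tone
#'
#' Deterministic periodic signals used as fixtures: pure sine, band-limited
#' sawtooth (harmonics to Nyquist with 1/k amplitudes), or a small
#' harmonic complex (8 partials, 1/k amplitudes). Peak amplitude 0.8.
#'
#' @param freq Fundamental in Hz (0 < freq < rate/2).
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param shape \code{"sine"}, \code{"sawtooth"} or \code{"harmonic"}.
#' @return An \code{audio_signal}.
#' @export
make_tone <- function(freq, duration = 1, rate = 44100,
                      shape = c("sine", "sawtooth", "harmonic")) {
  shape <- match.arg(shape)
  if (freq <= 0 || freq >= rate / 2)
    stop("freq must lie strictly between 0 and rate/2")
  n <- as.integer(round(duration * rate))
  tt <- (seq_len(n) - 1L) / rate
  x <- switch(shape,
    sine = sin(2 * pi * freq * tt),
    sawtooth = {
      kmax <- floor((rate / 2 - 1e-9) / freq)
      y <- numeric(n)
      for (k in seq_len(kmax)) y <- y + sin(2 * pi * k * freq * tt) / k
      y
    },
    harmonic = {
      kmax <- min(8L, floor((rate / 2 - 1e-9) / freq))
      y <- numeric(n)
      for (k in seq_len(kmax)) y <- y + sin(2 * pi * k * freq * tt) / k
      y
    })
  audio_signal(0.8 * x / max(abs(x)), rate)
}

#' Synthetic pitch glide
#'
#' Phase-continuous tone whose fundamental follows an exponential
#' trajectory from \code{f_start} to \code{f_end} (constant rate in
#' cents/second, which is how pitch glides are perceived as uniform).
#'
#' @param f_start,f_end Endpoint frequencies in Hz.
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param shape Waveform, as in \code{\link{make_tone}}.
#' @return An \code{audio_signal}.
#' @export
make_glide <- function(f_start, f_end, duration = 1, rate = 44100,
                       shape = c("sine", "sawtooth", "harmonic")) {
  shape <- match.arg(shape)
  for (f in c(f_start, f_end))
    if (f <= 0 || f >= rate / 2) stop("frequencies must be in (0, rate/2)")
  n <- as.integer(round(duration * rate))
  tt <- (seq_len(n) - 1L) / rate
  if (abs(f_end - f_start) < 1e-12) {
    phase <- 2 * pi * f_start * tt
  } else {
    r <- f_end / f_start
    # integral of f_start * r^(t/T) dt
    phase <- 2 * pi * f_start * duration / log(r) * (r^(tt / duration) - 1)
  }
  kmax <- switch(shape, sine = 1L,
                 sawtooth = floor((rate / 2 - 1e-9) / max(f_start, f_end)),
                 harmonic = min(8L, floor((rate / 2 - 1e-9) /
                                            max(f_start, f_end))))
  y <- numeric(n)
  for (k in seq_len(kmax)) y <- y + sin(k * phase) / k
  audio_signal(0.8 * y / max(abs(y)), rate)
}

#' Synthetic note sequence
#'
#' Concatenates harmonic tones with 10 ms raised-cosine cross-fades at the
#' joins, standing in for a sung phrase with known note onsets.
#'
#' @param f0s Fundamentals in Hz, one per note.
#' @param durations Note durations in seconds, same length.
#' @param rate Sampling rate in Hz.
#' @param shape Waveform, as in \code{\link{make_tone}}.
#' @return List with \code{signal} (an \code{audio_signal}) and
#'   \code{onsets} (note onset times in seconds, first at 0).
#' @export
make_note_sequence <- function(f0s, durations, rate = 44100,
                               shape = "harmonic") {
  if (length(f0s) != length(durations))
    stop("f0s and durations must have equal length")
  if (any(durations <= 0)) stop("durations must be > 0")
  onsets <- c(0, cumsum(durations))[seq_along(f0s)]
  total <- sum(durations)
  n <- as.integer(round(total * rate))
  y <- numeric(n)
  fade <- as.integer(round(0.010 * rate))
  for (i in seq_along(f0s)) {
    tone <- make_tone(f0s[i], durations[i], rate, shape)$samples
    m <- length(tone)
    env <- rep(1, m)
    nf <- min(fade, m %/% 2L)
    if (nf > 0L) {
      ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nf) - 0.5) / nf)
      if (i > 1L) env[seq_len(nf)] <- ramp
      if (i < length(f0s)) env[m - nf + seq_len(nf)] <- rev(ramp)
    }
    at0 <- as.integer(round(onsets[i] * rate))
    idx <- at0 + seq_len(m)
    idx <- idx[idx <= n]
    y[idx] <- y[idx] + (tone * env)[seq_along(idx)]
  }
  list(signal = audio_signal(pmin(1, pmax(-1, y)), rate), onsets = onsets)
}

#' Template-matching two-interval observer
#'
#' A simulated participant for 2-interval forced-choice trials. The
#' decision variable is the template projection of the difference between
#' the two presented profiles, normalized so the template response to a
#' SINGLE interval has unit variance under the stimulus distribution
#' (the evidence difference then has variance 2), plus additive internal
#' Gaussian noise; interval A is chosen when it exceeds the criterion.
#' Internal noise is therefore expressed in per-interval external-noise
#' units, matching the double-pass estimator's model and the convention
#' of the double-pass literature.
#'
#' @param template Numeric vector, one weight per profile segment.
#' @param internal_noise_sd Internal noise SD (>= 0), in external-noise
#'   units.
#' @param bias Decision criterion (0 = unbiased).
#' @return An \code{observer_model}.
#' @export
observer_model <- function(template, internal_noise_sd = 0, bias = 0) {
  if (any(!is.finite(template))) stop("template must be finite")
  if (internal_noise_sd < 0) stop("internal_noise_sd must be >= 0")
  structure(list(template = as.numeric(template),
                 internal_noise_sd = internal_noise_sd, bias = bias),
            class = "observer_model")
}

#' Simulate observer responses to profile pairs
#'
#' @param model An \code{observer_model}.
#' @param profile_a,profile_b Matrices (trials x segments) of stimulus
#'   profile values, e.g. pitch-shift cents per segment.
#' @param scale Per-interval normalization: the SD of
#'   \code{template \%*\% profile} under the stimulus distribution.
#'   Default: estimated from the supplied trials as
#'   \code{sd(template \%*\% (A - B)) / sqrt(2)}. Pass the analytic
#'   value for exact external-noise units.
#' @return Character vector of choices, \code{"A"} or \code{"B"}.
#' @export
simulate_observer <- function(model, profile_a, profile_b, scale = NULL) {
  stopifnot(inherits(model, "observer_model"))
  profile_a <- as.matrix(profile_a); profile_b <- as.matrix(profile_b)
  if (ncol(profile_a) != length(model$template) ||
      ncol(profile_b) != length(model$template))
    stop("profile length does not match template length")
  ev <- as.vector((profile_a - profile_b) %*% model$template)
  if (is.null(scale)) scale <- stats::sd(ev) / sqrt(2)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  d <- ev / scale +
    stats::rnorm(length(ev), 0, model$internal_noise_sd)
  ifelse(d > model$bias, "A", "B")
}

# SD of a Normal(mean, sd) truncated at +/- trunc*sd around the mean
truncated_normal_sd <- function(sd, trunc) {
  if (!is.finite(trunc)) return(sd)
  a <- trunc
  sd * sqrt(1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1))
}

# SD of log(t) when t ~ Normal(1, sd) truncated at +/- trunc*sd
truncated_lognorm_sd <- function(sd, trunc) {
  lo <- 1 - trunc * sd; hi <- 1 + trunc * sd
  if (lo <= 0) stop("truncation admits nonpositive stretch values")
  tgrid <- seq(lo, hi, length.out = 4001L)
  w <- stats::dnorm(tgrid, 1, sd); w <- w / sum(w)
  lg <- log(tgrid)
  sqrt(sum(w * lg^2) - sum(w * lg)^2)
}

# stimulus noise recipes of the two case studies
recipe_spec <- function(recipe) {
  switch(recipe,
    case1 = list(n_seg = 6L, std = 70, trunc = 2.2, domain = "linear",
                 dimension = "pitch"),
    case2 = list(n_seg = 6L, std = 0.4, trunc = 1.6, domain = "log",
                 dimension = "stretch"),
    stop("recipe must be 'case1' or 'case2'"))
}

#' Simulate a full reverse-correlation experiment
#'
#' Draws random stimulus profile pairs under a case-study noise recipe
#' (case 1: 6-point pitch noise, SD 70 cents truncated at 2.2 SD; case 2:
#' 6-segment stretch noise, SD 0.4 truncated at 1.6 SD, template matching
#' in the log-stretch domain), runs the observer on each pair, and tags a
#' final block that is presented twice for the double-pass analysis.
#'
#' @param recipe \code{"case1"} or \code{"case2"}.
#' @param observer An \code{observer_model}; its template must have the
#'   recipe's segment count.
#' @param n_trials Number of unique trials (>= 1).
#' @param double_pass_n Size of the repeated final block (default 33,
#'   capped at \code{n_trials}; 0 disables).
#' @param participant Participant label for the response table.
#' @return A \code{response_set} data frame (see
#'   \code{\link{response_set}}).
#' @export
simulate_experiment <- function(recipe = c("case1", "case2"), observer,
                                n_trials, double_pass_n = 33L,
                                participant = "sim") {
  recipe <- match.arg(recipe)
  stopifnot(inherits(observer, "observer_model"))
  if (n_trials < 1L) stop("n_trials must be >= 1")
  rs <- recipe_spec(recipe)
  k <- rs$n_seg
  if (length(observer$template) != k)
    stop("template length must be ", k, " for ", recipe)
  double_pass_n <- min(double_pass_n, n_trials)

  center <- neutral_value(rs$dimension)
  draw <- function(n) matrix(
    sample_truncated_gaussian(n * k, mean = center, std = rs$std,
                              trunc = rs$trunc), nrow = n)
  A <- draw(n_trials); B <- draw(n_trials)

  # analytic per-interval external-noise scale so internal noise is in
  # external units
  seg_sd <- if (rs$domain == "log") truncated_lognorm_sd(rs$std, rs$trunc)
            else truncated_normal_sd(rs$std, rs$trunc)
  scale <- seg_sd * sqrt(sum(observer$template^2))

  dec_a <- if (rs$domain == "log") log(A) else A
  dec_b <- if (rs$domain == "log") log(B) else B
  choice <- simulate_observer(observer, dec_a, dec_b, scale = scale)

  res <- response_set(participant = participant,
                      trial = seq_len(n_trials),
                      profile_a = A, profile_b = B,
                      choice = choice, pass = "main")
  if (double_pass_n > 0L) {
    idx <- (n_trials - double_pass_n + 1L):n_trials
    res$pass[idx] <- "double1"
    c2 <- simulate_observer(observer, dec_a[idx, , drop = FALSE],
                            dec_b[idx, , drop = FALSE], scale = scale)
    rep2 <- response_set(participant = participant,
                         trial = n_trials + seq_along(idx),
                         profile_a = A[idx, , drop = FALSE],
                         profile_b = B[idx, , drop = FALSE],
                         choice = c2, pass = "double2")
    res <- rbind(res, rep2)
  }
  res
}
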