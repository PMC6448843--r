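#' Breakpoint function
#'
#' A piecewise trajectory controlling a time-varying transformation
#' parameter. Two kinds are supported: \code{"ramp"} (linear interpolation
#' between breakpoints, clamped to the first/last value outside their
#' range) and \code{"square"} (one plateau per breakpoint, with linear
#' transitions of width \code{transition_time} centered on plateau
#' boundaries). Plateau boundaries default to the midpoints between
#' breakpoint times; explicit \code{boundaries} (length
#' \code{length(times) + 1}) override this, e.g. note on/offsets.
#'
#' @param times Breakpoint times in seconds, strictly increasing, >= 0.
#' @param values Breakpoint values (cents, stretch ratio, or dB).
#' @param kind \code{"ramp"} or \code{"square"}.
#' @param dimension \code{"pitch"}, \code{"stretch"} or \code{"gain"}.
#' @param transition_time Transition width in seconds (square only).
#' @param boundaries Optional explicit plateau boundaries (square only).
#' @return An object of class \code{bpf}.
#' @export
bpf <- function(times, values, kind = c("ramp", "square"),
                dimension = c("pitch", "stretch", "gain"),
                transition_time = 0.02, boundaries = NULL) {
  kind <- match.arg(kind)
  dimension <- match.arg(dimension)
  if (length(times) != length(values) || length(times) < 1L)
    stop("times and values must have equal length >= 1")
  if (any(times < 0) || (length(times) > 1L && any(diff(times) <= 0)))
    stop("times must be nonnegative and strictly increasing")
  if (!is.null(boundaries)) {
    if (kind != "square") stop("boundaries only apply to square BPFs")
    if (length(boundaries) != length(times) + 1L)
      stop("boundaries must have length(times) + 1 elements")
    if (any(diff(boundaries) <= 0)) stop("boundaries must be increasing")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind, dimension = dimension,
                 transition_time = as.numeric(transition_time),
                 boundaries = boundaries),
            class = "bpf")
}

# constant BPF at the given value
bpf_static <- function(value, dimension) {
  bpf(0, value, kind = "ramp", dimension = dimension)
}

neutral_value <- function(dimension) {
  switch(dimension, pitch = 0, stretch = 1, gain = 0,
         stop("unknown dimension: ", dimension))
}

#' @export
print.bpf <- function(x, ...) {
  cat(sprintf("<bpf[%s/%s]: %d breakpoints over [%.3g, %.3g] s>\n",
              x$dimension, x$kind, length(x$times), min(x$times),
              max(x$times)))
  invisible(x)
}

#' Evaluate a breakpoint function
#'
#' @param bpf A \code{bpf}.
#' @param t Time(s) in seconds (vectorized, \code{t >= 0}).
#' @return Interpolated value(s).
#' @export
evaluate_bpf <- function(bpf, t) {
  stopifnot(inherits(bpf, "bpf"))
  if (length(bpf$times) == 1L) return(rep(bpf$values, length(t)))
  if (bpf$kind == "ramp") {
    stats::approx(bpf$times, bpf$values, xout = t, rule = 2)$y
  } else {
    nb <- length(bpf$times)
    b <- bpf$boundaries
    if (is.null(b))
      b <- c(NA, (bpf$times[-1L] + bpf$times[-nb]) / 2, NA)
    # piecewise-linear profile: flat plateaus joined by linear
    # transitions of width transition_time centered on inner boundaries
    tr <- bpf$transition_time / 2
    span <- max(bpf$times) - min(bpf$times) + 1
    xs <- ys <- numeric(0)
    for (i in seq_len(nb)) {
      x0 <- if (i == 1L) bpf$times[1L] - span else b[i] + tr
      x1 <- if (i == nb) bpf$times[nb] + span else b[i + 1L] - tr
      if (x1 <= x0) { m <- (x0 + x1) / 2; x0 <- m - 1e-9; x1 <- m + 1e-9 }
      xs <- c(xs, x0, x1)
      ys <- c(ys, bpf$values[i], bpf$values[i])
    }
    stats::approx(xs, ys, xout = t, rule = 2)$y
  }
}

#' Breakpoint times for a segmented transformation
#'
#' Splits a duration into segments either of fixed length
#' (\code{winUnit = "s"}: \code{ceil(duration/winLen)} segments, last one
#' possibly shorter) or of fixed count (\code{winUnit = "n"}:
#' \code{numWin} equal segments). Returns one breakpoint per segment, at
#' the segment center. \code{numWin = 0} or \code{winLen = 0} denotes a
#' static transformation: a single breakpoint at mid-duration.
#'
#' @param duration Total duration in seconds (> 0).
#' @param spec A \code{transform_spec} (or list with \code{winUnit} and
#'   \code{winLen}/\code{numWin}).
#' @return List with \code{centers} (breakpoint times) and \code{edges}
#'   (segment boundaries, length \code{n + 1}).
#' @export
segment_times <- function(duration, spec) {
  if (duration <= 0) stop("duration must be > 0")
  if (identical(spec$winUnit, "n")) {
    n <- spec$numWin
    if (is.null(n)) stop("numWin required for winUnit 'n'")
    if (n == 0L) n <- 1L                     # static transformation
    if (n < 1L) stop("numWin must be >= 1")
    edges <- seq(0, duration, length.out = n + 1L)
  } else if (identical(spec$winUnit, "s")) {
    wl <- spec$winLen
    if (is.null(wl)) stop("winLen required for winUnit 's'")
    if (wl == 0) { edges <- c(0, duration) }  # static transformation
    else if (wl < 0) stop("winLen must be > 0")
    else {
      n <- ceiling(duration / wl - 1e-9)
      edges <- c(seq(0, by = wl, length.out = n), duration)
    }
  } else stop("winUnit must be 's' or 'n'")
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  list(centers = centers, edges = edges)
}

#' Truncated Gaussian sampling for breakpoint values
#'
#' Draws i.i.d. Normal(\code{mean}, \code{std}) values conditioned on
#' lying within \code{trunc} standard deviations of the mean, by rejection
#' sampling (so no probability mass piles up at the bounds). Uses R's
#' global RNG stream; seed with \code{set.seed()} for reproducibility.
#'
#' @param n Number of draws.
#' @param mean Center of the distribution.
#' @param std Standard deviation (>= 0; 0 returns \code{mean} exactly).
#' @param trunc Truncation in multiples of \code{std} (\code{Inf} = none).
#' @return Numeric vector of length \code{n}.
#' @export
sample_truncated_gaussian <- function(n, mean = 0, std = 1, trunc = Inf) {
  if (std < 0) stop("std must be >= 0")
  if (trunc <= 0) stop("trunc must be > 0")
  if (std == 0 || n == 0L) return(rep(mean, n))
  out <- stats::rnorm(n, mean, std)
  bad <- which(abs(out - mean) > trunc * std)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, std)
    bad <- bad[abs(out[bad] - mean) > trunc * std]
  }
  out
}

#' Transformation specification
#'
#' Parameters controlling the random breakpoint functions for one
#' dimension, mirroring the batch configuration keys.
#'
#' @param dimension \code{"pitch"}, \code{"stretch"} or \code{"gain"}.
#' @param winLen Segment length in seconds (used when
#'   \code{winUnit = "s"}; 0 = static).
#' @param numWin Number of segments (used when \code{winUnit = "n"};
#'   0 = static).
#' @param winUnit \code{"s"} or \code{"n"}.
#' @param std Standard deviation of breakpoint values, in the dimension's
#'   unit (cents, ratio, dB).
#' @param trunc Truncation in multiples of \code{std}.
#' @param BPFtype \code{"ramp"} or \code{"square"}.
#' @param trTime Transition time for square BPFs, seconds.
#' @return A \code{transform_spec}.
#' @export
transform_spec <- function(dimension = c("pitch", "stretch", "gain"),
                           winLen = 0.11, numWin = 6L, winUnit = "n",
                           std = 300, trunc = 1, BPFtype = "ramp",
                           trTime = 0.02) {
  dimension <- match.arg(dimension)
  if (!winUnit %in% c("s", "n")) stop("winUnit must be 's' or 'n'")
  if (std < 0) stop("std must be >= 0")
  if (trunc <= 0) stop("trunc must be > 0")
  if (!BPFtype %in% c("ramp", "square"))
    stop("BPFtype must be 'ramp' or 'square'")
  structure(list(dimension = dimension, winLen = winLen,
                 numWin = as.integer(numWin), winUnit = winUnit, std = std,
                 trunc = trunc, BPFtype = BPFtype, trTime = trTime),
            class = "transform_spec")
}

#' Generate a random breakpoint function
#'
#' Breakpoints sit at the segment centers implied by \code{spec}; values
#' are drawn from a truncated Gaussian centered on the neutral element of
#' the dimension (0 cents, ratio 1, 0 dB).
#'
#' @param duration Signal duration in seconds.
#' @param spec A \code{transform_spec}.
#' @param custom_times Optional explicit breakpoint times (e.g. note
#'   midpoints), overriding the segmentation.
#' @return A \code{bpf}.
#' @export
generate_random_bpf <- function(duration, spec, custom_times = NULL) {
  stopifnot(inherits(spec, "transform_spec"))
  if (is.null(custom_times)) {
    seg <- segment_times(duration, spec)
    times <- seg$centers
    boundaries <- if (spec$BPFtype == "square") seg$edges else NULL
  } else {
    times <- sort(custom_times)
    boundaries <- NULL
  }
  values <- sample_truncated_gaussian(length(times),
                                      mean = neutral_value(spec$dimension),
                                      std = spec$std, trunc = spec$trunc)
  bpf(times, values, kind = spec$BPFtype, dimension = spec$dimension,
      transition_time = spec$trTime, boundaries = boundaries)
}

#' Write / read a BPF as a two-column text file
#'
#' @param bpf A \code{bpf}.
#' @param path Output path.
#' @return \code{path} invisibly (\code{write_bpf}); a \code{bpf}
#'   (\code{read_bpf}).
#' @export
write_bpf <- function(bpf, path) {
  header <- sprintf("# dimension=%s kind=%s trTime=%g", bpf$dimension,
                    bpf$kind, bpf$transition_time)
  lines <- c(header, sprintf("%.9g\t%.9g", bpf$times, bpf$values))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bpf
#' @export
read_bpf <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  kv <- if (length(meta)) {
    parts <- strsplit(sub("^#\\s*", "", meta[1L]), "\\s+")[[1L]]
    stats::setNames(sub(".*=", "", parts), sub("=.*", "", parts))
  } else c(dimension = "pitch", kind = "ramp", trTime = "0.02")
  m <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  bpf(m[, 1L], m[, 2L], kind = kv[["kind"]],
      dimension = kv[["dimension"]],
      transition_time = as.numeric(kv[["trTime"]]))
}

#' Pitch-flattening breakpoint function
#'
#' Given an f0 contour, builds the pitch-shift BPF (in cents) that brings
#' the contour to a constant target frequency: at each contour time the
#' value is \code{1200 * log2(target / f0)}.
#'
#' @param contour Data frame with columns \code{time} and \code{f0} (Hz).
#' @param target Target frequency in Hz, or \code{"mean"} for the
#'   geometric mean of the voiced contour.
#' @return A ramp \code{bpf} in the pitch dimension.
#' @export
flatten_pitch_bpf <- function(contour, target = "mean") {
  if (is.null(nrow(contour)) || nrow(contour) == 0L)
    stop("contour must be non-empty")
  f0 <- contour$f0
  if (any(f0 <= 0)) stop("f0 values must be positive")
  if (identical(target, "mean")) target <- exp(mean(log(f0)))
  cents <- 1200 * log2(target / f0)
  tms <- contour$time
  if (length(tms) > 1L && any(diff(tms) <= 0)) {
    keep <- !duplicated(tms)
    tms <- tms[keep]; cents <- cents[keep]
  }
  bpf(tms, cents, kind = "ramp", dimension = "pitch")
}
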