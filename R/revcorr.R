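#' Response set for two-interval trials
#'
#' Builds the canonical trial table: one row per presentation, with the
#' two presented stimulus profiles in wide form (\code{A_1..A_k},
#' \code{B_1..B_k}), the observer's choice, and a pass tag
#' (\code{"main"}, or a matched pair of tags such as
#' \code{"double1"}/\code{"double2"} marking the repeated block of a
#' double-pass design).
#'
#' @param participant Participant identifier (recycled).
#' @param trial Trial indices.
#' @param profile_a,profile_b Matrices (trials x segments).
#' @param choice \code{"A"}/\code{"B"} per trial.
#' @param pass Pass tag per trial.
#' @return A data frame of class \code{response_set}.
#' @export
response_set <- function(participant, trial, profile_a, profile_b, choice,
                         pass = "main") {
  profile_a <- as.matrix(profile_a); profile_b <- as.matrix(profile_b)
  k <- ncol(profile_a)
  if (ncol(profile_b) != k) stop("profiles must have equal width")
  n <- nrow(profile_a)
  if (!all(choice %in% c("A", "B"))) stop("choice must be 'A' or 'B'")
  df <- data.frame(participant = rep_len(participant, n),
                   trial = trial,
                   stats::setNames(as.data.frame(profile_a),
                                   paste0("A_", seq_len(k))),
                   stats::setNames(as.data.frame(profile_b),
                                   paste0("B_", seq_len(k))),
                   choice = choice, pass = rep_len(pass, n))
  class(df) <- c("response_set", "data.frame")
  df
}

profile_cols <- function(trials, which = c("A", "B")) {
  which <- match.arg(which)
  cols <- grep(paste0("^", which, "_[0-9]+$"), names(trials), value = TRUE)
  cols[order(as.integer(sub(".*_", "", cols)))]
}

profile_matrix <- function(trials, which) {
  as.matrix(trials[, profile_cols(trials, which), drop = FALSE])
}

#' First-order temporal kernel
#'
#' The mean profile of the stimuli the observer selected minus the mean
#' profile of the stimuli they rejected, per segment. For ratio-valued
#' profiles (time-stretch factors) the kernel is computed in the log
#' domain: \code{mean(log t+) - mean(log t-)}.
#'
#' @param trials A \code{response_set} (single participant; repeat-pass
#'   presentations each count once).
#' @param domain \code{"linear"} or \code{"log"}.
#' @return A \code{kernel} object: per-segment values plus a
#'   \code{normalized} flag.
#' @export
compute_first_order_kernel <- function(trials,
                                       domain = c("linear", "log")) {
  domain <- match.arg(domain)
  if (is.null(nrow(trials)) || nrow(trials) == 0L)
    stop("empty response set")
  A <- profile_matrix(trials, "A")
  B <- profile_matrix(trials, "B")
  if (domain == "log") {
    if (any(A <= 0) || any(B <= 0))
      stop("log domain requires strictly positive profile values")
    A <- log(A); B <- log(B)
  }
  sel_a <- trials$choice == "A"
  selected <- rbind(A[sel_a, , drop = FALSE], B[!sel_a, , drop = FALSE])
  rejected <- rbind(B[sel_a, , drop = FALSE], A[!sel_a, , drop = FALSE])
  kernel(colMeans(selected) - colMeans(rejected))
}

#' Kernel container
#' @param values Per-segment kernel values.
#' @param normalized Whether values sum to 1 in absolute value.
#' @return A \code{kernel}.
#' @export
kernel <- function(values, normalized = FALSE) {
  structure(list(values = as.numeric(values),
                 normalized = isTRUE(normalized)), class = "kernel")
}

#' @export
print.kernel <- function(x, ...) {
  cat(sprintf("<kernel: %d segments%s>\n", length(x$values),
              if (x$normalized) ", normalized" else ""))
  print(signif(x$values, 4))
  invisible(x)
}

#' Normalize a kernel by its absolute sum
#'
#' @param k A \code{kernel} or numeric vector.
#' @return A \code{kernel} whose \code{sum(abs(values))} is 1.
#' @export
normalize_kernel <- function(k) {
  v <- if (inherits(k, "kernel")) k$values else as.numeric(k)
  s <- sum(abs(v))
  if (s == 0) stop("cannot normalize an all-zero kernel")
  kernel(v / s, normalized = TRUE)
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition for a complete participant x
#' segment matrix: \code{F = MS_segment / MS_(segment x subject)} with
#' degrees of freedom \code{(s - 1)} and \code{(s - 1)(n - 1)}. No
#' sphericity correction is applied.
#'
#' @param kernels Numeric matrix, participants in rows, segments in
#'   columns (complete; >= 2 of each).
#' @return List with \code{F}, \code{df} (length 2), \code{p}, and the
#'   underlying sums of squares.
#' @export
rm_anova <- function(kernels) {
  m <- as.matrix(kernels)
  if (anyNA(m)) stop("matrix must be complete (no missing cells)")
  n <- nrow(m); s <- ncol(m)
  if (n < 2L || s < 2L) stop("need >= 2 participants and >= 2 segments")
  grand <- mean(m)
  seg_means <- colMeans(m)
  subj_means <- rowMeans(m)
  ss_seg <- n * sum((seg_means - grand)^2)
  ss_subj <- s * sum((subj_means - grand)^2)
  resid <- m - outer(subj_means, seg_means, `+`) + grand
  ss_err <- sum(resid^2)
  df1 <- s - 1L
  df2 <- (s - 1L) * (n - 1L)
  Fval <- (ss_seg / df1) / (ss_err / df2)
  list(F = Fval, df = c(df1, df2),
       p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
       ss = c(segment = ss_seg, subject = ss_subj, error = ss_err))
}

#' Split-plot (mixed) ANOVA
#'
#' Within factor: segment; between factor: group (e.g. musicianship).
#' Returns the within-subject main effect of segment and the
#' segment-by-group interaction, both tested against the within-subject
#' error (segment x subject within group).
#'
#' @param kernels Participant x segment matrix.
#' @param group_labels One label per participant; exactly two or more
#'   groups, each with >= 2 members.
#' @return List with \code{F_within}, \code{F_interaction}, their dfs and
#'   p-values, and \code{F_between} for completeness.
#' @export
mixed_anova <- function(kernels, group_labels) {
  m <- as.matrix(kernels)
  if (anyNA(m)) stop("matrix must be complete")
  g <- factor(group_labels)
  if (length(g) != nrow(m)) stop("one group label per participant")
  if (any(table(g) < 2L)) stop("each group needs >= 2 members")
  n <- nrow(m); s <- ncol(m); ng <- nlevels(g)
  grand <- mean(m)

  seg_means <- colMeans(m)
  subj_means <- rowMeans(m)
  grp_means <- tapply(subj_means, g, mean)          # mean over segments too
  cell_means <- apply(m, 2L, function(col) tapply(col, g, mean)) # g x s

  ss_seg <- n * sum((seg_means - grand)^2)
  ss_grp <- s * sum(tabulate(g) * (grp_means - grand)^2)
  ss_subj_within <- s * sum((subj_means - grp_means[g])^2)
  ss_int <- 0
  for (gi in seq_len(ng)) {
    ni <- sum(g == levels(g)[gi])
    for (si in seq_len(s)) {
      ss_int <- ss_int + ni * (cell_means[gi, si] - grp_means[gi] -
                                 seg_means[si] + grand)^2
    }
  }
  ss_total <- sum((m - grand)^2)
  ss_err_within <- ss_total - ss_grp - ss_subj_within - ss_seg - ss_int

  df_seg <- s - 1L
  df_int <- (s - 1L) * (ng - 1L)
  df_errw <- (s - 1L) * (n - ng)
  df_grp <- ng - 1L
  df_errb <- n - ng

  ms_errw <- ss_err_within / df_errw
  F_within <- unname((ss_seg / df_seg) / ms_errw)
  F_int <- unname((ss_int / df_int) / ms_errw)
  F_between <- unname((ss_grp / df_grp) / (ss_subj_within / df_errb))

  list(F_within = F_within, df_within = c(df_seg, df_errw),
       p_within = stats::pf(F_within, df_seg, df_errw, lower.tail = FALSE),
       F_interaction = F_int, df_interaction = c(df_int, df_errw),
       p_interaction = stats::pf(F_int, df_int, df_errw,
                                 lower.tail = FALSE),
       F_between = F_between, df_between = c(df_grp, df_errb),
       p_between = stats::pf(F_between, df_grp, df_errb,
                             lower.tail = FALSE))
}

#' Double-pass agreement
#'
#' Matches the two passes of the repeated block (tags other than
#' \code{"main"}; trials pair in presentation order within each tag) and
#' returns the fraction of pairs answered identically, together with the
#' overall fraction of interval-A choices over the repeated
#' presentations (response bias).
#'
#' @param trials A \code{response_set} containing exactly two non-main
#'   pass tags with equal trial counts.
#' @return List with \code{agreement} and \code{prop_a}, both in [0, 1].
#' @export
double_pass_agreement <- function(trials) {
  tags <- setdiff(unique(trials$pass), "main")
  if (length(tags) != 2L)
    stop("expected exactly two repeat-pass tags, found ", length(tags))
  p1 <- trials[trials$pass == tags[1L], , drop = FALSE]
  p2 <- trials[trials$pass == tags[2L], , drop = FALSE]
  if (nrow(p1) != nrow(p2) || nrow(p1) == 0L)
    stop("repeat passes do not pair one-to-one")
  list(agreement = mean(p1$choice == p2$choice),
       prop_a = mean(c(p1$choice, p2$choice) == "A"))
}

# ---- internal-noise model -------------------------------------------------
# Signal-detection model for the double pass: on each trial the external
# evidence in each interval has unit variance, so the evidence difference
# s ~ N(0, 2) is fixed across the two passes; each pass adds fresh
# internal (late) noise e ~ N(0, sigma) — sigma in per-interval
# external-noise units, the double-pass literature's convention — and
# responds A iff s + e > b. Predicted P(A) and P(agreement) follow by
# integrating the per-trial binomial over s. The (sigma, b) grid is
# inverted by nearest prediction. Integration over s uses a fine fixed
# grid, giving a deterministic table accurate to ~1e-6 (no Monte-Carlo
# error).

noise_table_env <- new.env(parent = emptyenv())

internal_noise_table <- function(sigma_grid = seq(0, 5, by = 0.05),
                                 bias_grid = seq(-2.5, 2.5, by = 0.05)) {
  key <- paste0(length(sigma_grid), "x", length(bias_grid))
  if (!is.null(noise_table_env[[key]])) return(noise_table_env[[key]])
  xs <- sqrt(2) * seq(-8, 8, length.out = 1601L)   # s ~ N(0, sqrt(2))
  wx <- stats::dnorm(xs / sqrt(2)); wx <- wx / sum(wx)
  nc <- length(sigma_grid) * length(bias_grid)
  tab <- data.frame(sigma = rep(sigma_grid, times = length(bias_grid)),
                    bias = rep(bias_grid, each = length(sigma_grid)),
                    p_a = numeric(nc), agreement = numeric(nc))
  i <- 0L
  for (b in bias_grid) {
    for (sg in sigma_grid) {
      i <- i + 1L
      pr <- if (sg == 0) as.numeric(xs > b)
            else stats::pnorm((xs - b) / sg)
      tab$p_a[i] <- sum(wx * pr)
      tab$agreement[i] <- sum(wx * (pr^2 + (1 - pr)^2))
    }
  }
  noise_table_env[[key]] <- tab
  tab
}

#' Estimate internal noise from double-pass statistics
#'
#' Inverts the late-noise signal-detection model: finds the internal
#' noise SD (in units of the per-interval external evidence SD) and
#' criterion whose
#' predicted double-pass agreement and interval-A proportion are nearest
#' the observed pair. Observed agreement below the model's floor of 0.5
#' is flagged as unreliable.
#'
#' @param agreement Observed fraction of agreeing pairs (0..1).
#' @param interval_bias Observed fraction of interval-A choices (0..1).
#' @return List with \code{sigma}, \code{bias}, the predicted pair, and
#'   \code{reliable}.
#' @export
estimate_internal_noise <- function(agreement, interval_bias = 0.5) {
  if (agreement < 0 || agreement > 1 || interval_bias < 0 ||
      interval_bias > 1)
    stop("agreement and interval_bias must lie in [0, 1]")
  tab <- internal_noise_table()
  d2 <- (tab$agreement - agreement)^2 + (tab$p_a - interval_bias)^2
  best <- tab[which.min(d2), ]
  reliable <- agreement >= 0.5 - 1e-9
  if (!reliable)
    warning("observed agreement below the chance-consistent floor; ",
            "estimate unreliable")
  list(sigma = best$sigma, bias = best$bias,
       predicted_agreement = best$agreement, predicted_prop_a = best$p_a,
       reliable = reliable)
}

#' Kernel convergence curve
#'
#' Correlation between the kernel computed from the first \code{n} trials
#' and the kernel from all trials, for \code{n = step, 2 step, ...}. The
#' final point is 1 by construction.
#'
#' @param trials A \code{response_set}.
#' @param step Trial-count increment (default 20).
#' @param domain Kernel domain, as in
#'   \code{\link{compute_first_order_kernel}}.
#' @return Data frame with columns \code{n} and \code{correlation}.
#' @export
kernel_convergence <- function(trials, step = 20L,
                               domain = c("linear", "log")) {
  domain <- match.arg(domain)
  N <- nrow(trials)
  if (N < 2L * step) stop("need at least 2 * step trials")
  full <- compute_first_order_kernel(trials, domain)$values
  if (stats::sd(full) == 0)
    stop("degenerate (constant) kernel: correlation undefined")
  ns <- unique(c(seq(step, N, by = step), N))
  cors <- vapply(ns, function(n) {
    part <- compute_first_order_kernel(trials[seq_len(n), , drop = FALSE],
                                       domain)$values
    if (stats::sd(part) == 0) return(NA_real_)
    stats::cor(part, full)
  }, numeric(1))
  data.frame(n = ns, correlation = cors)
}

#' Read a response table from CSV
#'
#' Reads a trial table in the package's wide layout, or any CSV that can
#' be mapped onto it via \code{mapping}: a list with entries
#' \code{participant}, \code{trial}, \code{choice}, \code{pass} (column
#' names, or a constant for \code{pass}) and either \code{a_prefix} /
#' \code{b_prefix} or explicit \code{a_cols} / \code{b_cols}.
#'
#' @param path CSV path.
#' @param mapping Optional column mapping (default: native layout).
#' @return A \code{response_set}.
#' @export
read_response_table <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(mapping))
    mapping <- list(participant = "participant", trial = "trial",
                    choice = "choice", pass = "pass",
                    a_prefix = "A_", b_prefix = "B_")
  pick_cols <- function(prefix, cols) {
    if (!is.null(cols)) return(cols)
    found <- grep(paste0("^", prefix), names(df), value = TRUE)
    found[order(suppressWarnings(
      as.numeric(sub(paste0("^", prefix), "", found))))]
  }
  a_cols <- pick_cols(mapping$a_prefix, mapping$a_cols)
  b_cols <- pick_cols(mapping$b_prefix, mapping$b_cols)
  if (length(a_cols) == 0L || length(a_cols) != length(b_cols))
    stop("could not identify matching A/B profile columns")
  pass <- if (!is.null(mapping$pass) && mapping$pass %in% names(df))
    as.character(df[[mapping$pass]]) else
      if (!is.null(mapping$pass_constant)) mapping$pass_constant else "main"
  response_set(participant = as.character(df[[mapping$participant]]),
               trial = df[[mapping$trial]],
               profile_a = df[, a_cols, drop = FALSE],
               profile_b = df[, b_cols, drop = FALSE],
               choice = as.character(df[[mapping$choice]]),
               pass = pass)
}

#' Write a response table to CSV
#' @param trials A \code{response_set}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_response_table <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}
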