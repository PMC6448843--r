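#' Batch configuration
#'
#' Assembles the configuration driving \code{\link{process_batch}}. The
#' key names mirror the flat configuration-file keys
#' (\code{numFiles}, \code{outPath}, \code{chain}, \code{transf}, and one
#' \code{transform_spec} per listed dimension).
#'
#' @param numFiles Number of output stimuli (>= 1).
#' @param outPath Output directory.
#' @param chain Apply the transformations in series (\code{TRUE}) or
#'   write one independent output per transformation (\code{FALSE}).
#' @param transf Character vector of dimensions, in application order,
#'   among \code{"pitch"}, \code{"stretch"}, \code{"gain"}.
#' @param specs Named list of \code{transform_spec}s, one per dimension
#'   in \code{transf}.
#' @param seed Integer seed for the run.
#' @return A \code{batch_config}.
#' @export
batch_config <- function(numFiles, outPath, chain = TRUE, transf, specs,
                         seed = 1L) {
  if (numFiles < 1L) stop("numFiles must be >= 1")
  if (length(transf) == 0L) stop("transf must name >= 1 transformation")
  if (!all(transf %in% c("pitch", "stretch", "gain")))
    stop("unknown dimension in transf")
  missing <- setdiff(transf, names(specs))
  if (length(missing))
    stop("missing transform spec for: ", paste(missing, collapse = ", "))
  structure(list(numFiles = as.integer(numFiles), outPath = outPath,
                 chain = isTRUE(chain), transf = transf, specs = specs,
                 seed = as.integer(seed)),
            class = "batch_config")
}

#' Read a batch configuration file
#'
#' Accepts YAML or JSON with top-level keys \code{numFiles},
#' \code{outPath}, \code{chain}, \code{transf}, \code{seed}, and one
#' nested map per dimension holding the \code{transform_spec} keys
#' (\code{winLen}, \code{numWin}, \code{winUnit}, \code{std},
#' \code{trunc}, \code{BPFtype}, \code{trTime}).
#'
#' @param path Path to the configuration file.
#' @param outPath Optional override of the configured output directory.
#' @return A \code{batch_config}.
#' @export
read_batch_config <- function(path, outPath = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  transf <- unlist(raw$transf)
  specs <- lapply(stats::setNames(transf, transf), function(d) {
    s <- raw[[d]]
    if (is.null(s)) stop("missing spec block for dimension '", d, "'")
    defaults <- list(winLen = 0.11, numWin = 6L, winUnit = "n",
                     std = neutral_spread(d), trunc = Inf,
                     BPFtype = "ramp", trTime = 0.02)
    s <- utils::modifyList(defaults, s)
    # YAML 1.1 reads a bare `n` as FALSE; map it back to the unit flag
    if (is.logical(s$winUnit)) s$winUnit <- if (s$winUnit) "y" else "n"
    transform_spec(dimension = d, winLen = s$winLen, numWin = s$numWin,
                   winUnit = s$winUnit, std = s$std, trunc = s$trunc,
                   BPFtype = s$BPFtype, trTime = s$trTime)
  })
  batch_config(numFiles = raw$numFiles,
               outPath = if (is.null(outPath)) raw$outPath else outPath,
               chain = isTRUE(raw$chain), transf = transf, specs = specs,
               seed = if (is.null(raw$seed)) 1L else raw$seed)
}

neutral_spread <- function(dimension)
  switch(dimension, pitch = 100, stretch = 0.2, gain = 3)

#' Apply a chain of breakpoint-function transformations
#'
#' @param signal An \code{audio_signal}.
#' @param bpfs List of \code{bpf}s (each tagged with its dimension),
#'   applied in order. An empty list returns the input unchanged.
#' @return The transformed \code{audio_signal}.
#' @export
apply_chain <- function(signal, bpfs) {
  stopifnot(inherits(signal, "audio_signal"))
  for (b in bpfs) {
    stopifnot(inherits(b, "bpf"))
    signal <- switch(b$dimension,
                     pitch = pitch_shift(signal, b),
                     stretch = time_stretch(signal, b),
                     gain = apply_gain(signal, b),
                     stop("unknown dimension: ", b$dimension))
  }
  signal
}

#' Batch generation of randomized stimuli
#'
#' Generates \code{numFiles} randomly transformed variants of a base
#' sound. In chained mode each output applies every listed transformation
#' in series, re-rolling an independent breakpoint function per dimension
#' and output; in parallel mode each transformation yields its own
#' independent output file. Every WAV is accompanied by one two-column
#' BPF log per applied transformation, and the run writes a manifest CSV.
#'
#' @param base Path to a mono WAV base sound, or an \code{audio_signal}.
#' @param config A \code{batch_config}.
#' @return Invisibly, the manifest data frame (columns: file, dimension
#'   chain, seed, BPF paths).
#' @export
process_batch <- function(base, config) {
  stopifnot(inherits(config, "batch_config"))
  signal <- if (inherits(base, "audio_signal")) base else load_wav(base)
  base_name <- if (is.character(base))
    tools::file_path_sans_ext(basename(base)) else "base"
  dir.create(config$outPath, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$outPath))
    stop("cannot create output directory: ", config$outPath)
  set.seed(config$seed)
  run_id <- sprintf("r%08x", config$seed)

  rows <- list()
  width <- max(2L, nchar(as.character(config$numFiles)))
  for (i in seq_len(config$numFiles)) {
    idx <- formatC(i, width = width, flag = "0")
    if (config$chain) {
      out <- signal
      bpf_paths <- character(0)
      for (d in config$transf) {
        b <- generate_random_bpf(duration(out), config$specs[[d]])
        out <- apply_chain(out, list(b))
        bp <- file.path(config$outPath,
                        sprintf("%s.%s.%s.%s.bpf.txt", base_name, run_id,
                                idx, d))
        write_bpf(b, bp)
        bpf_paths <- c(bpf_paths, bp)
      }
      wav <- file.path(config$outPath,
                       sprintf("%s.%s.%s.wav", base_name, run_id, idx))
      save_wav(normalize_on_overflow(out), wav)
      rows[[length(rows) + 1L]] <- data.frame(
        file = wav, transforms = paste(config$transf, collapse = "+"),
        seed = config$seed, bpf = paste(bpf_paths, collapse = ";"))
    } else {
      for (d in config$transf) {
        b <- generate_random_bpf(duration(signal), config$specs[[d]])
        out <- apply_chain(signal, list(b))
        stem <- sprintf("%s.%s.%s.%s", base_name, run_id, idx, d)
        bp <- file.path(config$outPath, paste0(stem, ".bpf.txt"))
        wav <- file.path(config$outPath, paste0(stem, ".wav"))
        write_bpf(b, bp)
        save_wav(normalize_on_overflow(out), wav)
        rows[[length(rows) + 1L]] <- data.frame(
          file = wav, transforms = d, seed = config$seed, bpf = bp)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest,
                   file.path(config$outPath,
                             sprintf("manifest.%s.csv", run_id)),
                   row.names = FALSE)
  log_run(config, run_id, manifest)
  invisible(manifest)
}

# peak-normalize only when synthesis overflowed the unit range
normalize_on_overflow <- function(signal) {
  peak <- max(abs(signal$samples))
  if (peak > 1) audio_signal(signal$samples / peak, signal$rate)
  else signal
}

log_run <- function(config, run_id, manifest) {
  path <- file.path(config$outPath, sprintf("run.%s.log", run_id))
  lines <- c(sprintf("run %s  seed=%d  numFiles=%d  chain=%s", run_id,
                     config$seed, config$numFiles, config$chain),
             sprintf("transf: %s", paste(config$transf, collapse = ", ")),
             sprintf("%d files written", nrow(manifest)))
  writeLines(lines, path)
  invisible(path)
}

#' Build a case-study stimulus from a base sound
#'
#' Reproduces the two stimulus recipes used in the speech-intonation and
#' musical-rhythm experiments. \code{"case1"}: the base voice is
#' pitch-flattened to its (geometric) mean f0, offset by a constant
#' \code{offset_cents} (+/- 20 cents in the experiment), then overlaid
#' with 6-point ramp Gaussian pitch noise (SD 70 cents, truncated at 2.2
#' SD). \code{"case2"}: notes (delimited by \code{onsets}) are first
#' stretched to equal duration, then overlaid with per-note square
#' Gaussian stretch noise (SD 0.4, truncated at 1.6 SD, 0.1 s
#' transitions).
#'
#' @param base An \code{audio_signal} (voiced for case 1).
#' @param recipe \code{"case1"} or \code{"case2"}.
#' @param onsets Note onset times in seconds (case 2 only; first note
#'   starts at \code{onsets[1]}, last note ends at the signal end).
#' @param offset_cents Constant pitch offset for case 1 (default +20).
#' @param noise_std,noise_trunc Override the recipe's noise parameters
#'   (e.g. \code{noise_std = 0} for a noiseless stimulus).
#' @return List with \code{signal} (the stimulus) and \code{profile}
#'   (the noise breakpoint values entering the response table).
#' @export
make_case_study_stimulus <- function(base, recipe = c("case1", "case2"),
                                     onsets = NULL, offset_cents = 20,
                                     noise_std = NULL,
                                     noise_trunc = NULL) {
  recipe <- match.arg(recipe)
  stopifnot(inherits(base, "audio_signal"))
  rs <- recipe_spec(recipe)
  std <- if (is.null(noise_std)) rs$std else noise_std
  trunc <- if (is.null(noise_trunc)) rs$trunc else noise_trunc

  if (recipe == "case1") {
    contour <- estimate_pitch_contour(base)
    flat <- flatten_pitch_bpf(contour, target = "mean")
    out <- pitch_shift(base, flat)
    spec <- transform_spec("pitch", numWin = rs$n_seg, winUnit = "n",
                           std = std, trunc = trunc, BPFtype = "ramp")
    noise <- generate_random_bpf(duration(out), spec)
    combined <- bpf(noise$times, noise$values + offset_cents,
                    kind = "ramp", dimension = "pitch")
    out <- pitch_shift(out, combined)
    list(signal = out, profile = noise$values, offset = offset_cents)
  } else {
    if (is.null(onsets) || length(onsets) < 1L)
      stop("case2 requires a note-onset list")
    edges <- c(onsets, duration(base))
    durs <- diff(edges)
    if (any(durs <= 0)) stop("onsets must be increasing and in range")
    target <- mean(durs)
    eq <- bpf(times = (edges[-1L] + edges[-length(edges)]) / 2,
              values = target / durs, kind = "square",
              dimension = "stretch", transition_time = 0.02,
              boundaries = edges)
    out <- time_stretch(base, eq)
    n_notes <- length(durs)
    new_edges <- onsets[1L] + target * (0:n_notes)
    values <- sample_truncated_gaussian(n_notes, mean = 1, std = std,
                                        trunc = trunc)
    noise <- bpf(times = (new_edges[-1L] + new_edges[-(n_notes + 1L)]) / 2,
                 values = values, kind = "square", dimension = "stretch",
                 transition_time = 0.1, boundaries = new_edges)
    out <- time_stretch(out, noise)
    list(signal = out, profile = values, note_duration = target)
  }
}
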