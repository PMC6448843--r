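# config-driven batch generation, chaining, case-study recipes

write_test_config <- function(out_dir, numFiles = 3L, chain = TRUE,
                              transf = c("stretch", "pitch"),
                              std = list(stretch = 0.2, pitch = 70),
                              seed = 99L) {
  lines <- c(
    sprintf("numFiles: %d", numFiles),
    sprintf("outPath: %s", out_dir),
    sprintf("chain: %s", tolower(chain)),
    sprintf("transf: [%s]", paste(transf, collapse = ", ")),
    sprintf("seed: %d", seed),
    "stretch: {numWin: 4, winUnit: n, std: %STD_S%, trunc: 1.5, BPFtype: square, trTime: 0.02}",
    "pitch: {numWin: 6, winUnit: n, std: %STD_P%, trunc: 2.2, BPFtype: ramp}",
    "gain: {numWin: 4, winUnit: n, std: 3, trunc: 2, BPFtype: square, trTime: 0.02}")
  lines <- sub("%STD_S%", std$stretch %||% 0.2, lines)
  lines <- sub("%STD_P%", std$pitch %||% 70, lines)
  f <- tempfile(fileext = ".yaml")
  writeLines(lines, f)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

base_wav <- function(dir = tempdir()) {
  f <- file.path(dir, "base220.wav")
  save_wav(make_tone(220, 0.4, 22050, "harmonic"), f)
  f
}

test_that("process_batch writes stimuli, BPF logs and a manifest", {
  out <- withr::local_tempdir()
  cfg <- read_batch_config(write_test_config(out))
  man <- process_batch(base_wav(), cfg)
  expect_equal(nrow(man), 3L)
  expect_true(all(file.exists(man$file)))
  # chained run: one BPF log per applied transformation
  for (bp in strsplit(man$bpf, ";")) {
    expect_length(bp, 2L)
    expect_true(all(file.exists(bp)))
  }
  expect_length(list.files(out, pattern = "^manifest.*csv$"), 1L)
  # outputs are loadable audio of plausible duration (random stretch)
  y <- load_wav(man$file[1])
  expect_gt(duration(y), 0.1)
})

test_that("parallel mode emits one output per transformation", {
  out <- withr::local_tempdir()
  cfg <- read_batch_config(write_test_config(out, numFiles = 2L,
                                             chain = FALSE))
  man <- process_batch(base_wav(), cfg)
  expect_equal(nrow(man), 4L)                 # 2 files x 2 dimensions
  expect_setequal(unique(man$transforms), c("stretch", "pitch"))
})

test_that("neutral batch reproduces the base sound", {
  out <- withr::local_tempdir()
  cfg <- read_batch_config(write_test_config(
    out, numFiles = 3L, std = list(stretch = 0, pitch = 0)))
  base <- base_wav()
  man <- process_batch(base, cfg)
  x <- load_wav(base)
  for (f in man$file) {
    y <- load_wav(f)
    expect_gt(trimmed_cor(y$samples, x$samples), 0.99)
  }
})

test_that("batch runs are deterministic given base, config and seed", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  base <- base_wav()
  m1 <- process_batch(base, read_batch_config(write_test_config(out1)))
  m2 <- process_batch(base, read_batch_config(write_test_config(out2)))
  for (i in seq_len(nrow(m1))) {
    expect_identical(load_wav(m1$file[i])$samples,
                     load_wav(m2$file[i])$samples)
    b1 <- strsplit(m1$bpf[i], ";")[[1]]; b2 <- strsplit(m2$bpf[i], ";")[[1]]
    for (j in seq_along(b1))
      expect_identical(readLines(b1[j]), readLines(b2[j]))
  }
})

test_that("config errors are explicit", {
  expect_error(batch_config(0, tempdir(), TRUE, "pitch",
                            list(pitch = transform_spec("pitch"))),
               "numFiles")
  expect_error(batch_config(1, tempdir(), TRUE, character(0), list()),
               "transf")
  expect_error(batch_config(1, tempdir(), TRUE, c("pitch", "stretch"),
                            list(pitch = transform_spec("pitch"))),
               "missing")
  expect_error(batch_config(1, tempdir(), TRUE, "spectral", list()),
               "unknown")
})

test_that("apply_chain composes transformations in order", {
  tone <- make_tone(440, 0.5, 22050, "sine")
  expect_identical(apply_chain(tone, list()), tone)

  chain <- list(bpf(0, 1200, "ramp", "pitch"),
                bpf(0, -6.0206, "ramp", "gain"))
  y <- apply_chain(tone, chain)
  expect_lt(abs(peak_freq(y) - 880), fft_bin_width(y))
  expect_equal(rms(y$samples) / rms(tone$samples), 0.5, tolerance = 0.02)

  sg <- list(bpf(0, 2, "ramp", "stretch"), bpf(0, 0.5, "ramp", "stretch"))
  z <- apply_chain(tone, sg)
  expect_lt(abs(duration(z) - 0.5) / 0.5, 0.05 + 2 * 256 / 22050)
})

test_that("case-study recipes produce the documented stimuli", {
  set.seed(123)
  # case 1: flatten + offset, no noise -> f0 exactly offset from target
  saw <- make_tone(110, 0.6, 22050, "sawtooth")
  cs1 <- make_case_study_stimulus(saw, "case1", noise_std = 0,
                                  offset_cents = 20)
  f0 <- exp(mean(log(estimate_pitch_contour(cs1$signal)$f0)))
  expect_lt(abs(1200 * log2(f0 / (110 * 2^(20 / 1200)))), 5)
  expect_true(all(cs1$profile == 0))

  # noise profiles stay within +/- 2.2 SD of 70 cents
  for (i in 1:20) {
    csn <- make_case_study_stimulus(saw, "case1")
    expect_true(all(abs(csn$profile) <= 154))
    expect_length(csn$profile, 6L)
  }

  # case 2: zero noise equalizes all note durations
  ns <- make_note_sequence(c(196, 262, 294, 330, 370, 440),
                           c(0.75, 0.25, 1, 1, 1, 2) * 0.3, 22050)
  cs2 <- make_case_study_stimulus(ns$signal, "case2",
                                  onsets = ns$onsets, noise_std = 0)
  expect_equal(duration(cs2$signal), duration(ns$signal),
               tolerance = 0.02)
  # note boundaries recovered from the f0 track sit at equal spacing
  contour <- estimate_pitch_contour(cs2$signal, frame_step = 0.005)
  jumps <- contour$time[which(abs(diff(1200 * log2(contour$f0 /
                                contour$f0[1]))) > 60)]
  jumps <- jumps[c(TRUE, diff(jumps) > 0.05)]
  expect_length(jumps, 5L)
  spacing <- diff(c(0, jumps))
  expect_lt(max(abs(spacing - cs2$note_duration)),
            0.05)
  expect_error(make_case_study_stimulus(ns$signal, "case2"), "onset")
})
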