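Package: revoc
Title: Randomized Prosody Stimuli and Reverse-Correlation Analysis with a
    Phase Vocoder
Version: 0.1.0
Authors@R:
    person("revoc", "maintainers", email = "revoc@example.org",
           role = c("aut", "cre"))
Description: Generates large sets of randomly modulated variants of a base
    speech or music recording by driving a phase-locked phase vocoder with
    stochastic breakpoint functions over pitch (cents), local duration
    (stretch ratio) and amplitude (dB). Includes the reverse-correlation
    analysis pipeline used with such stimuli: first-order temporal kernels,
    repeated-measures and split-plot ANOVA, double-pass response agreement
    and signal-detection estimation of internal noise, plus deterministic
    synthetic fixtures (tones, glides, note sequences, simulated
    two-interval observers) so the whole methodology can be validated
    without human data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
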