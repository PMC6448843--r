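---
title: "Randomized prosody stimuli and reverse correlation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized prosody stimuli and reverse correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(revoc)
```

`revoc` has two halves: a phase-vocoder stimulus engine that randomizes
the pitch, duration and amplitude contours of a base recording, and the
reverse-correlation pipeline that turns the resulting two-interval
choices back into an estimate of the listener's internal template. This
vignette records the models, the parameters that matter, and the places
where the design was genuinely open — and what the synthetic test suite
does and does not establish.

## 1. The signal model

A mono signal $x$ is analyzed with a symmetric window $h$ of $N$ samples
at hop $R_a$:

$$X(\tau_u, \Omega_k) = \sum_n h(n)\, x(\tau_u + n)\, e^{-j\Omega_k n},
\qquad \Omega_k = 2\pi k/N .$$

Synthesis is the inverse DFT per frame (carrying the $1/N$), windowed
again and overlap-added at hop $R_s$; the result is divided by the
overlap-added squared window, so reconstruction is exact for every
window/hop whose squared overlap-add stays strictly positive (the
suite verifies $\|\mathrm{istft}(\mathrm{stft}(x)) - x\|_\infty <
10^{-8}$; in practice it is at machine precision).

**Window defaults.** The published description of the tool does not state
window type, length or overlap. We use a periodic Hann window of about
46 ms (2048 samples at 44.1 kHz, scaled as the nearest power of two at
other rates) and $R_s = N/4$ — the textbook choice for Hann analysis with
75% overlap. Both are configurable; nothing in the suite depends on the
specific values. Frames are centered by reflect-padding $N/2$ samples at
both ends so the first frame sits at $t = 0$.

**Transformations.**

* *Time stretch.* The analysis hop varies per frame as $R_a(u) = R_s /
  t(\tau_u)$ against the constant synthesis hop, so local duration scales
  by $t$; output length is $\int t(\tau)\,d\tau$, computed exactly from
  the per-sample stretch profile. Breakpoint times are interpreted on the
  *input* timeline, which keeps segments aligned with the recording's
  events (notes, syllables) — the property the note-aligned recipes need.
* *Pitch shift.* Stretch by $p(\tau) = 2^{\mathrm{cents}/1200}$, then
  resample by $1/p$. For time-varying $p$ the resampler's read position
  in the stretched signal at output sample $m$ is the accumulated
  stretch integral $\sum_{i \le m} p_i$ — with the consequence that
  output time equals input time *exactly*, so duration is preserved by
  construction even for arbitrary contours. Formant/spectral-envelope
  preservation is deliberately not applied.
* *Amplitude.* A time–frequency mask multiplies frame magnitudes by
  $10^{g(\tau_u)/20}$ with phases untouched.

**Phase locking.** When frames move in time, phases are propagated only
at spectral peaks (strict maxima over their four frequency neighbors);
each remaining bin follows the phase *rotation* of the peak whose region
of influence (bounded by midpoints between adjacent peaks) contains it.
The per-peak advance is the principal-value-unwrapped analysis phase
increment rescaled by the hop ratio. The exact instantaneous-frequency
estimator is unspecified in the source description; this one satisfies
the contracts in the suite (clean sinusoids stay > 40 dB above the
background after stretching; partials stay within one FFT bin).
Hermitian symmetry is re-imposed on the half-spectrum after phase
modification so the synthesis stays real.

## 2. Breakpoint functions

A BPF holds strictly increasing times and one value per breakpoint, in
cents, stretch ratio, or dB. *Ramp* BPFs interpolate linearly and clamp
outside their range. *Square* BPFs are plateaus joined by linear
transitions of width `trTime` centered on plateau boundaries; boundaries
default to midpoints between breakpoints and can be given explicitly
(note onsets). Segmentation is either `winUnit = "s"` (fixed segment
length, `ceil(duration/winLen)` segments, shorter last) or `"n"` (fixed
count); `numWin = 0`/`winLen = 0` denotes a static transformation.
Breakpoints sit at segment centers; whether the released tool samples
ramp endpoints at centers or edges is unknowable from the description,
and with clamped extrapolation the two differ only in the outer half
segments.

Random values are drawn from a Gaussian centered on the neutral element
(0 cents, ratio 1, 0 dB) and truncated at `trunc` multiples of the SD by
**rejection sampling**, not hard clipping: "clipped at ±k SD" is
ambiguous, and rejection preserves the Gaussian shape instead of piling
mass at the bounds. Stretch values are sampled in the linear domain
(centered at 1) even though the analysis works in log stretch — exactly
as the rhythm experiment specifies. With SD 100 cents and no truncation,
68.3% of draws fall within ±1 semitone; the acceptance report recomputes
this each run.

The pitch-flattening helper estimates an f0 contour (frame-wise
normalized autocorrelation, 60–500 Hz default range, parabolic lag
refinement, voicing threshold 0.5 on the biased ACF — the bias taper is
kept deliberately, since it suppresses octave-down errors) and emits the
correcting BPF $1200\log_2(f_\mathrm{target}/f_0(t))$. It is a
validation-grade tracker for clean, voiced material, not a production
one; users can supply external contours.

## 3. Experiment recipes

*Speech intonation (case 1):* flatten the base voice to its geometric
mean f0, add a constant ±20-cent offset, then 6-point ramp pitch noise
with SD 70 cents truncated at 2.2 SD. Only the noise profile enters the
response table — the constant offset is a task crutch, not a regressor.
*Musical rhythm (case 2):* stretch each note (delimited by its onset
list) to the mean note duration, then per-note square stretch noise with
SD 0.4 truncated at 1.6 SD and 0.1 s transitions. A session presents 280
unique trials plus the final 33-trial block twice (313 presentations).

## 4. Reverse correlation

The first-order kernel is `mean(selected) − mean(rejected)` per segment,
computed in log stretch for ratio-valued profiles; kernels are
normalized by their absolute sum *per participant* before averaging or
ANOVA (the published order of operations). The one-way repeated-measures
ANOVA uses the classical decomposition
$F = \mathrm{MS}_{seg}/\mathrm{MS}_{seg\times subj}$ with df $(s-1),
(s-1)(n-1)$ and no sphericity correction (the published dfs are
uncorrected); the split-plot version tests segment and segment×group
against the within-subject error. Both are verified to $10^{-9}$ against
`stats::aov` with `Error(subj/seg)` strata on random matrices, balanced
and unbalanced.

**Internal noise.** The double-pass model: per trial the template
response to each interval has unit variance under the stimulus
distribution, so the evidence difference is $s \sim N(0, 2)$, fixed
across passes; each pass adds fresh late noise $\varepsilon \sim
N(0, \sigma)$ and responds A iff $s + \varepsilon > b$. $\sigma$ is in
*per-interval* external-noise units — the double-pass literature's
convention, and the only reading under which a $\sigma = 1$ observer
produces the expected ~0.73 mean agreement on 33-pair blocks. Predicted
(agreement, P(A)) are one-dimensional Gaussian integrals; rather than
the Monte-Carlo table originally envisaged (10^5 draws per cell) they
are evaluated by fixed 1601-point quadrature on a (σ ∈ [0,5], b ∈
[−2.5, 2.5], step 0.05) grid — deterministic and accurate to ~10⁻⁶ —
and inverted by nearest prediction. Agreement below 0.5 is impossible
under the model and is flagged unreliable. Simulation recovery: medians
over repeated synthetic double passes land within a few percent of
planted σ ∈ {0.5, 1, 2} (the suite enforces 30%).

Convergence curves report the Pearson correlation (the unqualified
"correlation" of the source) between partial- and full-data kernels.

## 5. What the synthetic world does and does not establish

The generators emulate: tones/glides/note sequences with known f0 and
onsets; stimulus profile noise with the exact case-study parameters; and
a template-matching SDT observer — choices are driven by the profiles
(the quantities the analysis regresses on), not by the rendered audio,
matching how the pipeline treats trials. Audio enters the tests through
the transform contracts and the recipe round trips (flattening a glide,
equalizing note durations), not through the 700-trial loops.

A green suite therefore establishes that the *method* is implemented
correctly: the vocoder honors its duration/pitch/gain contracts, the
sampling law is as stated, and the analysis recovers planted templates
(cosine similarity > 0.9 at 700 trials with internal noise 1.1, the mean
human value) and planted internal noise. It does **not** establish the
published human findings — final-rise interrogative kernels, shortened
first-note representations, F(6,24) = 35.84, mean internal noise 1.1 —
which are properties of the human response tables distributed as a
separate supplementary download; given those CSVs, `read_response_table`
with a column mapping feeds the identical pipeline.

## 6. Numerical choices and limitations

* Analysis frame positions are rounded to integer samples; phase
  propagation uses the actual rounded hops, so no sub-sample phase error
  accumulates.
* The variable resampler uses linear interpolation of the ~40×
  oversampled stretched signal — adequate below ~2 kHz fundamentals
  (tests pass at 25-cent tolerance with margin); the standalone
  `resample()` is exact Fourier resampling.
* Square-BPF transitions are linear in the parameter (cents/ratio/dB),
  i.e. geometric in frequency and duration.
* Degenerate inputs: all-zero kernels refuse normalization; empty
  spectrograms, non-positive stretch factors, unpaired double-pass
  blocks, and incomplete ANOVA matrices all error explicitly.
* Known artifacts inherent to the approach and deliberately uncorrected:
  formant shift under large pitch shifts, transient smearing under large
  stretches. The intended regime is small random perturbations.
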