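---
title: "Random temporal sampling: simulation and classification-image analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random temporal sampling: simulation and classification-image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temposample)
```

## The paradigm

In a random temporal sampling experiment, an observer identifies a briefly
displayed word (a 4AFC task: the target plus three foils) embedded in white
noise. The word is spatially band-pass filtered into one of four
spatial-frequency (SF) conditions — Butterworth bands centered at 1.2, 2.4,
4.8 and 9.6 cycles/degree with half-power cutoffs at (0.9–1.5), (1.8–3.0),
(3.6–6.0) and (7.2–12) cpd — and its visibility oscillates randomly within
the 200 ms display: each of the 24 frames (120 Hz) mixes the
contrast-scaled word and the noise field with a weight given by the trial's
*SNR sampling function*,

$$\mathrm{frame}_t = s_t \cdot \mathrm{signal}_c + (1 - s_t) \cdot \mathrm{noise}.$$

The sampling function is a sum of sinusoids at 5–55 Hz (5 Hz steps) with
random amplitudes and phases, normalized to span exactly [0, 0.75]. Because
those frequencies sit on exact DFT bins of a 24-sample window, the waveform
carries no spectral power at DC, at the 60 Hz Nyquist bin, or between the
component frequencies — a property the test suite asserts exactly.

Reverse correlation over many trials then asks: *when* (and at which SNR
oscillation frequencies) did visibility matter for getting the word right?
The answer is a classification image (CI): the weighted subtraction of the
sampling functions (or their Morlet power maps) of error trials from those
of correct trials.

## What the package provides

* **Stimulus engine** — word rendering from a built-in configurable
  sans-serif bitmap face, radial Butterworth band-pass filtering via the
  FFT, uniform white-noise fields, SNR sampling functions, frame
  composition, and the 4AFC distractor assignment (greedy
  similarity-maximizing pass followed by a spread-balancing swap pass,
  under the ≤ 6 reuse cap).
* **Experiment simulator** — the full trial schedule (400 words presented
  8 times each, twice per condition, no repeats within a block; 3200
  trials over 4 sessions of 4 × 200-trial blocks) and the per-condition
  adaptive contrast staircase (start 35%, step 16% halved at each
  reversal down to 1%, evaluated on the last 10 trials of the tested
  condition once 20 trials have elapsed).
* **Synthetic observer** — the data generator used throughout the tests.
* **CI pipeline** — raw CIs, bootstrap z-scoring, group averaging,
  Gaussian smoothing, and a max-statistic Pixel test.
* **Signature classifier** — the four feature recodings of individual
  CIs, the discrimination-index feature ranking, the stepwise
  leave-one-out linear SVM, and the per-condition signature values.

## The synthetic observer

No human data ship with the package, so simulations rest on a parametric
observer whose correctness probability depends on the trial's sampling
function through condition-specific sensitivity kernels:

$$d = \frac{c}{100}\Big(\langle k^{\mathrm{time}}_{\mathrm{cond}},\, s\rangle
      + \langle k^{\mathrm{tf}}_{\mathrm{cond}},\, W(s)\rangle\Big), \qquad
  p(\mathrm{correct}) = \tfrac14 + \big(\tfrac34 - \lambda\big)\,
  \mathrm{logistic}\big(\beta (d - \kappa)\big),$$

where $c$ is the contrast in percent, $W(s)$ the 11 × 24 Morlet power map
of the sampling function, $\lambda$ a lapse rate, and 1/4 the 4AFC
guessing floor. The logistic link was chosen because it gives closed-form
values for the boundary tests (zero kernels, extreme criterion); any
monotone link would serve. Either drive term can be zeroed to isolate one
pathway.

`make_paperlike_observer()` builds the packaged default: gaussian-bump
kernels whose temporal peaks are ordered from the highest SF condition
(earliest, frame 4 ≈ 29 ms) to the lowest (late, frame 14 ≈ 113 ms), a
distinct oscillation-frequency peak per condition in the time–frequency
kernels, and higher gain for the two intermediate SF conditions, which are
the most informative bands for reading. All kernels have unit L2 norm
before gain weighting.

**Calibration.** The psychometric constants default to slope $\beta = 24$
and criterion $\kappa = 0.33$. They were fixed once by a calibration sweep
(slopes 8–32 across several schedule seeds) scoring two desiderata
jointly: (i) the staircase settles with the intermediate SF conditions
needing roughly two-thirds the contrast of the extreme ones (the simulated
defaults settle near 16/11/12/19 %), and (ii) the temporal kernels remain
recoverable from 800 trials per condition (see below). These are generator
properties, not tuned test thresholds, and they are not revisited.

### What the generator does and does not emulate

The simulator reproduces the paradigm's design exactly: schedule
constraints, staircase dynamics, per-trial independent sampling functions
and noise seeds. It does *not* emulate several features of real observers:
response times, sequential dependencies (fatigue, learning), lapses are
off by default, inter-observer kernel variability (all simulated
participants share one kernel set; they differ only in trial noise), or
any interaction between the word identity and difficulty. Passing
recovery and classification tests therefore demonstrates correctness of
the analysis chain under the generative model, not that the pipeline's
statistical power matches what human data would afford.

## The CI pipeline and its numerical choices

* **"Weighted subtraction"** is implemented as the difference of class
  means (each class weighted internally by its own trial count). A
  count-weighted pooled difference is selectable via `weighting =
  "pooled"`; the choice matters only when class sizes are very uneven.
* **Morlet transform**: three-cycle complex Morlet wavelets
  ($\sigma_t = n_{\mathrm{cycles}} / 2\pi f$), unit-energy normalized, at
  5–55 Hz in 5 Hz steps; squared magnitude of the convolution at each
  frame. Edges use zero padding with no cone-of-influence masking — a
  24-sample window is too short to discard columns — so frequency
  selectivity should be read from interior columns; tests do.
* **Bootstrap z-scoring**: the null resamples trials with replacement
  while assigning correct/error labels at random with class counts
  preserved (the resampling unit is the trial, recorded in the output's
  provenance). 1000 resamples by default; under an uninformative labeling
  the resulting z values are calibrated to mean 0, SD 1 within tight
  bands (tested).
* **Smoothing**: Gaussian kernels specified by FWHM ($\sigma =$ FWHM /
  2.355) of 19.6 ms for time-domain CIs and 29.3 ms × 17.7 Hz for
  time–frequency CIs, converted to cell units (frame = 8.33 ms, row =
  5 Hz), reflective boundaries, kernel normalized to unit sum so constant
  maps pass through unchanged.
* **Order of operations**: raw CI → bootstrap z (per participant) →
  average across participants → smooth → Pixel test.
* **Pixel test**: the familywise-error-controlling threshold is obtained
  from a max-statistic permutation null rather than random-field theory:
  each permutation re-assigns every participant's correct/error labels
  (class counts preserved), recomputes and re-standardizes the
  per-participant CIs with their stored bootstrap moments, averages,
  smooths identically, and records the maximum |z|. The two-tailed
  threshold is the upper order statistic at $1 - \alpha$; thresholds are
  symmetric about zero by construction. This controls FWER without
  random-field assumptions; the result records `mode =
  "max_stat_permutation"` so an RFT mode could be added without ambiguity.
  Under a zero-kernel observer the realized FWER over 500 null replicates
  is ~0.03–0.04 at $\alpha = 0.05$ (slightly conservative, as expected
  for a max-statistic test with estimated standardization).

## Feature spaces and the classifier

Individual (unsmoothed) z-scored CIs are recoded four ways, with feature
counts fixed by the geometry: 24 time-domain frames; a 12 × 12
frequency-by-phase grid of the time-domain CI (144); the 11 × 24
time–frequency map (264); and a grid per oscillation-frequency row of the
time–frequency map (11 × 144 = 1584). The 12 × 12 grid geometry — 12
positive DFT frequencies (5–60 Hz) × 12 phase bins of 30° covering
[−180°, 180°) — is the only one consistent with the 144 and 1584 counts.
Each frequency's folded (Parseval-consistent) power lands in exactly one
phase bin, so the grid total equals the series' non-DC spectral power.

Features are ranked by the discrimination index: the variance of the
condition means (population form, i.e. divided by the number of
conditions — this matches the index's worked definition) over the pooled
within-condition variance. Ties break toward the lower column index;
zero-within/nonzero-between columns rank first with an infinite index.

The stepwise SVM enters features in ranking order, scoring each step by
leave-one-out cross-validation (linear kernel, cost 1, features z-scored
on each training fold), and stops at 90% accuracy or feature exhaustion.
The default ranks once on the full matrix — the literal reading of the
procedure — which leaks selection information into the folds;
`rank_in_fold = TRUE` recomputes the ranking inside every fold for a
leakage-free estimate. Both are tested; they may legitimately differ.

Condition signatures re-express the retained features per condition as
the signed, squared deviation of the condition mean from the grand mean
over the pooled error variance, normalized by the global maximum absolute
value into [−1, 1]. The squared-deviation statistic is non-negative, yet
the illustration spans −1 to 1; the sign of (condition mean − grand mean)
is therefore re-attached before normalization — flagged here because the
alternative (unsigned) reading cannot be excluded. Display contrast dims
linearly with distance from ±1 down to a floor of 0.3, and exact-zero
cells are flagged omitted.

## Design choices on open points

* **Mixture convention**: "linear summation" is pinned as the convex form
  $s \cdot \mathrm{signal}_c + (1-s) \cdot \mathrm{noise}$, which keeps
  luminance bounded and makes $s = 0$ (pure noise) and $s = 1$
  interpretable. Contrast scales the filtered word's deviation from mean
  luminance, in percent of the maximum displayable deviation.
* **Butterworth order** defaults to 2 and is exposed in `filter_specs()`.
  The band-pass magnitude is the canonical analog form with exact
  half-power at both cutoffs.
* **Word count**: 400 words exactly fill the 3200-trial budget at 8
  presentations each; the schedule builder takes the word count as a
  parameter rather than resolving how a 424-word list maps onto 3200
  trials.
* **Staircase cadence**: evaluated after every trial (past trial 20) for
  the condition just tested, requiring ≥ 10 prior trials of that
  condition; exact 50% windows leave the contrast unchanged; contrast is
  clamped to [1, 100] %.
* **Degenerate draws**: an (astronomically unlikely) all-zero amplitude
  draw in the sampling-function generator re-draws from an offset seed
  rather than dividing by ~0.
* **Fonts**: the original display font is not redistributable; the
  package renders from its own bitmap face with the word width and
  x-height as configurable metrics (defaults 3.4° and 0.75°, ±10% glyph
  tolerance).
* **Seeds**: every stochastic stage takes an explicit seed; stage seeds
  derive from one master seed via a fixed linear-congruential splitting
  rule (`derive_seed()`), so whole runs are byte-reproducible.

## Problem sizes used by the test suite

Tests run on synthetic cohorts sized for tight feedback while preserving
every contract under test: the shared cohort is 16 participants × 800
trials (100 words, 4 sessions × 4 blocks × 50 trials; 200
trials/condition) with 300 bootstrap resamples; kernel-recovery checks
use one participant at the full 3200-trial geometry (800 trials per
condition, the paradigm's per-condition count); FWER calibration uses 500
null replicates of 4 participants × 120 trials with 199 permutations; the
classifier tests cap the stepwise procedure at 50 steps. The acceptance
script runs the full 16 × 3200-trial geometry.

## Known limitations

* The Pixel test is permutation-based; no closed-form random-field
  threshold is provided.
* Simulated participants share one kernel set, so between-participant
  replicability — the property the classifier is designed to expose in
  real data — is built in rather than emergent.
* The short 24-sample window makes high-frequency Morlet rows at edge
  frames partially edge-attenuated; no cone-of-influence mask is applied.
* Empirical accuracies from the original human dataset are not
  reproducible from simulation and are not targets of the test suite.
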