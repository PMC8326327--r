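---
title: "Methods: simulating and decoding a two-step P300 destination selector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding a two-step P300 destination selector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300tour)
```

## The paradigm

A visual oddball interface presents six on-screen stimuli that flash one at
a time in randomized order while the user attends one of them. Each flash of
the attended ("target") stimulus elicits a P300 — a positive event-related
potential peaking roughly 300–400 ms after the flash, largest over midline
parieto-occipital sites. A selection is one six-way decision: every stimulus
flashes N times (N = 30 per training block, N = 20 online), each flash's EEG
epoch is classified target/nontarget, the per-stimulus label sums form a
*blink vote*, and the highest vote wins. The game applies this twice per
trial: the first selection picks a continent, the second a destination from
that continent's six places (a 6 × 6 catalogue of 36 destinations).

Flash onsets are spaced 187.5 ms apart (onset-to-onset). The flash
randomization draws one random permutation of the six stimuli per round, and
swaps a round's head away from the previous round's tail so the same
stimulus never flashes twice in a row; this keeps the per-stimulus counts
exactly balanced while behaving like the usual single-stimulus P300
randomization.

## The synthetic-data generator

`simulate_session()` produces ground-truthed sessions with the protocol's
exact bookkeeping: a training session of six sequential blocks (each
stimulus targeted once, 30 flashes per stimulus, 180 target / 900 nontarget
epochs) and online sessions of six trials with two 20-flash selections each,
targets drawn uniformly. Blocks are separated by 2 s of plain background
(instruction/video time; configurable — the protocol's actual pause lengths
are not part of the marker stream and do not affect decoding).

The signal model is deliberately simple and fully parameterized:

* **Background**: per-channel 1/f ("pink") Gaussian noise, synthesized in
  the frequency domain (flat below 0.1 Hz), scaled to a per-channel RMS of
  `noise_scale` microvolts. Channels are independent.
* **Target response** (`erp_template()`): a Gaussian bump of peak amplitude
  5 uV, latency 350 ms, temporal SD 80 ms, added at every target flash and
  only there. Per-event latency jitter (SD 20 ms) and amplitude jitter
  (SD 1 uV) emulate trial-to-trial variability. The scalp topography is a
  fixed non-negative weight per channel,
  `(0.12 + 0.88 * ap^1.5) * (1 - 0.7 * lateral)` (anterior-posterior
  coordinate `ap`, laterality `lateral`, normalized to max 1), giving the
  midline-parietal dominance typical of the P300 and the front-to-back
  ordering Fz < Cz < Pz < Oz along the midline.

**Choice of the default noise level.** The template's amplitude and shape
are fixed as above; the only free scale is the background RMS. We set
`noise_scale = 6` uV once, by requiring that the full decoding chain applied
to simulated subjects operates in the same accuracy-versus-blinks regime the
application reports on real subjects (about 45–50% correct selections with a
single flash per stimulus, rising through ~75–95% at N = 5–15 to near 100%
at N = 20). Higher noise (8–10 uV) pushes the whole curve well below that
regime, lower noise (≤ 5 uV) saturates it. The value is a generator default,
not a fitted parameter, and everything downstream treats it as data.

**Simulation rate.** Sessions are synthesized at 512 Hz. Acquisition
hardware in this class of experiment samples at 2,048 Hz, and
`resample()` handles that rate (it is exercised in the tests); but the
decoding chain's first step reduces to 512 Hz, so synthesizing above it
only costs memory without changing any downstream value.

**What the generator does not emulate.** Real EEG has spatially correlated
noise, eye-blink and muscle artifacts, alpha rhythms, non-Gaussian
amplitude distributions, multi-component ERPs (N1/P2/N2 preceding the
P300), target-to-target-interval effects on P300 amplitude, and
nonstationarity across a 50-minute session. Passing tests on this generator
therefore demonstrate the *correctness of the computation* — bookkeeping,
filters, selection logic, statistics — and a parameter-recovery property
(the chain finds what was injected), not the clinical performance of the
decoder on recorded data.

## The signal-processing chain

`preprocess_session()` implements, in order: down-sampling to 512 Hz
(6th-order zero-phase Butterworth anti-alias at 0.8 x the new Nyquist, then
decimation), common average reference, 0.5–10 Hz band-pass, epoching, and
baseline correction.

Numerical choices worth recording:

* The band-pass is realized as a 2nd-order high-pass at 0.5 Hz cascaded
  with a 4th-order low-pass at 10 Hz, each applied forward-backward. A
  single 8-coefficient band-pass recursion at a normalized corner of
  0.5/256 is numerically fragile; the cascade is stable and keeps the
  passband ripple below 1 dB.
* Epochs are the half-open window `[200, 600)` ms after flash onset, so an
  epoch holds `floor(0.4 * sfreq)` samples — 204 at 512 Hz, 51 on the
  128 Hz feature grid. Onsets are mapped to samples by `round(onset * sfreq)`
  with 0-based time; these conventions make epoch and feature counts
  reproducible to the sample.
* The epoch window starts after the stimulus, so no pre-stimulus baseline
  exists inside it; the baseline statistic is therefore the whole-epoch
  per-channel mean (configurable to the median). This is the only reading
  consistent with a chain that epochs before baseline-correcting.
* The 128 Hz feature grid is obtained by plain decimation (every 4th
  sample): the signal is already band-limited to 10 Hz, so no further
  anti-aliasing is needed, and decimation commutes with flattening.
* No artifact detection or rejection of any kind: every epoch is used.

`to_features()` flattens channel-major and records a feature map
(feature index → channel, time), which later localizes selected features
per channel.

## SWLDA

`stepwise_select()` is classic forward–backward stepwise regression of the
0/1 label on feature columns, computed incrementally with a Gram–Schmidt
orthogonalization of the included design (so each forward sweep over the
~1,600 candidates is a vector operation, not 1,600 separate fits). Entry
requires partial p < 0.05; after each entry, included features with
coefficient p > 0.10 are removed, worst first. The removal threshold and
the 60-feature cap are the conventional SWLDA settings for P300 feature
vectors of this size; both are exposed as parameters. Ties on the minimal
p-value break to the lowest feature index, making the path deterministic.
Candidates that are numerically collinear with the included set are skipped
with a log note. Note that with removal at 0.10 a retained feature's final
p-value may lie between 0.05 and 0.10 — the suite asserts the 0.10 bound,
which is the invariant this classical recipe actually guarantees.

`fit_linear()` refits OLS weights on the selected columns (re-estimation
after selection is the default; the stepwise coefficients themselves are
available by fitting on the same set). With labels coded {0, 1}, the linear
score is an estimate of the posterior target probability, so the hard-label
threshold defaults to 0.5 with ties labelled 1; the 1:5 class imbalance is
absorbed by the coding. The threshold is a parameter because vote-based
selection only needs *relative* per-stimulus counts.

## Selection scoring

Each selection is scored independently against its instructed target id: if
the continent step errs, the game still proceeds with the (wrong) continent
screen and the place step is scored against the instructed place index on
whatever screen is shown. This matches an online protocol that scores 12
selections per session as independent events. Vote ties break to the lowest
stimulus index.

## Evaluation statistics

* `wolpaw_itr()` implements the standard Wolpaw bit rate (with
  `0 log2 0 := 0`); below-chance accuracies return the formula's value
  unmodified. Published ITR tables in this literature print accuracy either
  truncated to whole percent (online tables) or at two decimals
  (subsampling tables); feeding those printed values reproduces every
  published cell to ±0.01 bits/min.
* `subsample_accuracy()` draws N epochs per stimulus per selection without
  replacement, re-votes, and averages 10 repeats; at the maximal N the draw
  is exhaustive and the repeat SD is exactly 0.
* Response times per N (6.62, 11.37, 17.75, 23.87, 30.5 s for
  N = 1, 5, 10, 15, 20) are configuration constants: they embed an
  empirically measured system delay that cannot be derived from the ISI.
* `summarize_likert()` uses the population (divide-by-n) SD — the
  convention that reproduces published questionnaire summaries such as
  4.3 ± 0.78.

## ERP statistics

`erp_stat()` contrasts target and nontarget epochs at one channel
(default Cz): pointwise means with standard errors, a per-timepoint
*permutation* test whose statistic is the pooled two-sample t (10,000
label shuffles by default, add-one p-value estimator so p is never 0), and
a Benjamini–Yekutieli step-up mask at q = 0.05. BY rather than BH because
neighboring timepoints are strongly dependent; the BY mask is always a
subset of the BH mask. A purely parametric per-timepoint t-test is
available via `parametric = TRUE`. Timepoints with zero pooled variance
get p = 1 with a warning. No cluster-level correction is applied — the
control is per timepoint.

One subtlety of the synthetic topography: its weights are constrained
non-negative, so the common average reference removes most of the midline
common mode and leaves Cz with only a small contrast. ERP waveform
summaries on synthetic data are therefore best run on the recording
reference (`preprocess_session(..., car = FALSE)`), where the Cz effect is
unattenuated; real recordings, whose ERP topographies integrate to roughly
zero across the scalp, do not share this artifact. The decoding chain
itself always uses CAR.

## Problem sizes used in the test suite

The acceptance-style checks simulate a 10-subject cohort (seeds 1–10), each
subject contributing one training session (1,080 epochs) and two online
sessions (24 selections, 2,880 epochs), plus a matched cohort with a
zero-amplitude template for the chance-level control; permutation-test
calibration uses 100 null runs of 20 + 20 epochs at 51 timepoints with 400
permutations each. These sizes keep the whole suite comfortably within a
desktop run while leaving the statistical margins wide (the recovery
cohort's mean replay accuracy sits several points above the 95% bound, and
the null cohort's 240 selections give a ±4.7-point binomial band around
16.7% chance).

## Known limitations

* The generator's independence across channels makes spatial filtering
  (CAR) behave differently than on real, spatially correlated noise; see
  the ERP note above.
* The EDF writer quantizes to 16 bits over each channel's observed range —
  lossless for analysis purposes (the quantization step is ~1/65,000 of the
  range) but not bit-identical storage; event tables round-trip exactly via
  the companion CSV.
* Epoch containers serialize via RDS, a single-file R-native format; no
  HDF5 dependency is used.
* No cross-validated hyperparameter search, regularized variants, or
  adaptive (dynamic-stopping) flash counts: the pipeline is a single fixed
  recipe by design, matching the evaluation it reproduces.
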