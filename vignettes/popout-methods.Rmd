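---
title: "Methods: simulating and decoding degraded-speech pop-out experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding degraded-speech pop-out experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(popout)
```

## The scientific problem

When a listener hears a heavily degraded sentence, reads its written
transcription, and then hears the same degraded sentence again, the second
presentation often sounds dramatically clearer — the "pop-out" effect.
popout packages the complete analysis workflow used to study the
neurophysiology of this effect: reconstruction of the speech envelope from
EEG with a backward temporal-response-function (TRF) decoder, band-limited
spectral and induced-power analysis with cluster-based permutation
statistics, and pupillometry. Because the human recordings that motivated
this workflow cannot be regenerated at a desk, the package is built around
a synthetic-data generator that emulates the experiment end to end with
*injectable, known condition effects*, so that every analysis stage can be
validated by parameter recovery.

## The emulated experiment

The generator reproduces the structure of a two-presentation
clarity-rating study:

* **Stimuli.** 80 pairs of synthetic "sentences" (160 stimuli), each a
  parametric formant object: four formant frequency/amplitude trajectories
  sampled at a 100 Hz control rate plus a nonnegative syllable envelope
  with dominant energy at 2–8 Hz. A pair's second member is a bounded
  perturbation of the first (formant scale within ±10%, independent
  syllable timing), which preserves the pair structure that the
  incorrect-prior condition requires without any language assets. Each
  sentence lasts 3.5 s and is concatenated three times (10.5 s). Three
  acoustic versions exist: clear (harmonic source shaped by the formant
  resonances), sine-wave speech (SWS: one sinusoid per formant), and
  7-band noise-vocoded speech (NVS).
* **Design.** 96 trials per participant in 6 blocks of 16: 2 stimulus
  types (SWS/NVS) × 3 prior conditions. The written text shown between the
  two presentations of a trial is the correct sentence (P+), the unheard
  pair mate (P−), or hash marks (P0). Four of the five stimulus lists feed
  the informative-prior cells, the fifth is split across the two P0 cells;
  the list-to-condition mapping rotates across participants as a 5 × 5
  Latin square.
* **Recordings.** 64-channel EEG at 500 Hz (idealized spherical 10-10
  template, 85 mm radius; TP9/TP10 serve as mastoids), two-eye pupil
  traces at 300 Hz with blink gaps, ordinal 1–4 clarity ratings from a
  latent-threshold model, and a continuous clear-speech "audiobook"
  narrative used solely for decoder training.

### The forward EEG model

Simulated trial EEG is a sum of interpretable components
(`simulate_trial_eeg()`):

* an **envelope-tracking component**: the 2–8 Hz auditory envelope of the
  presented stimulus convolved with a rank-one channel × lag kernel
  (lags 0–300 ms, fronto-central topography, unit energy), scaled by the
  trial's `tracking_gain`;
* **theta (4–9 Hz)** and **alpha (10–15 Hz)** filtered-noise oscillations
  with fixed frontal-midline and parieto-occipital topographies, whose
  amplitude is multiplied by `theta_gain`/`alpha_gain` during the stimulus
  window (smooth on/off ramps of ~200 ms);
* **1/f background noise**, spatially independent across channels;
* **source noise**: 1/f noise sharing the tracking kernel's topography.
  This term is what bounds decodable SNR — noise orthogonal to the signal
  subspace can be projected out by a multivariate decoder, noise in the
  same generators cannot;
* a deterministic **onset-evoked transient** (damped 7 Hz oscillation over
  0–0.7 s), identical across trials, so induced-power analysis has a
  nontrivial evoked component to remove.

Component amplitudes (`default_noise_params()`: tracking 0.25, theta and
alpha 1.5, background 1, source 1.5, onset 0.5) were chosen once so that
the simulation behaves like the field's data: single-trial reconstruction
scores fall around *r* ≈ 0.3 at baseline, the band oscillations dominate
their spectral bands (so a 25% theta suppression is not masked by
envelope-tracking leakage into 4–9 Hz), and noiseless simulations decode
essentially perfectly. `noise_scale` multiplies all stochastic components
for graded-degradation experiments.

Condition effects are multiplicative gains applied on the second
presentation only (`condition_effects()`); the packaged "paper-like"
configuration (`paper_like_effects()`) is tracking_gain(P+) = 1.5,
theta_gain(P+) = 0.75, alpha_gain(P+/P−) = 1.3, pupil_gain(P+/P−) = 1.5,
rating_shift(P+) = 2. The neutral configuration makes the three priors
statistically exchangeable, which is the basis of every null-calibration
check.

### What the generator does and does not emulate

Passing recovery tests on this generator shows that the analysis chain is
correct and calibrated — it does not show that real EEG obeys a rank-one
linear tracking model. Real data add: non-Gaussian artifacts (ocular,
muscle; the paper's ICA step is interactive and out of scope here),
between-participant anatomy and montage variation, non-stationary
oscillatory dynamics, and linguistic structure in the stimuli. The
generator's stimuli are formant objects, not language; nothing in the
package models intelligibility itself.

## The auditory model

`extract_envelope()` implements a spectro-temporal excitation pattern
(STEP) front end: resample to 22.05 kHz; outer/middle-ear band-pass
(2nd-order Butterworth, 450 Hz–8.5 kHz, forward pass); 128 linear
4th-order gammatone filters, ERB-spaced from 50 Hz to 8 kHz (the filters
are applied as analytic frequency responses by FFT multiplication);
per band half-wave rectification and a 100 Hz low-pass 2nd-order
Butterworth; square-root compression. The cochleagram
(`step_cochleagram()`) stores the log10 of the compressed band envelopes
with a floor of 1e-6 so silence stays finite. The **auditory envelope**
sums the square-root-compressed (pre-log) band envelopes — summing after
the log would let the silence floor dominate — then resamples to 100 Hz
and band-passes to 2–8 Hz with a two-pass windowed-sinc FIR
(~1.2 s impulse response, Hamming window). Rectified band signals are
decimated to ~1 kHz with an anti-aliased polyphase FIR before the 100 Hz
smoothing; resampling uses windowed-sinc anti-alias filtering plus linear
interpolation throughout.

## EEG preprocessing

Deterministic conditioning only (no interactive artifact screening):
epoching into [−5, +15] s windows with per-channel demeaning; two-pass
4th-order Butterworth high-pass (1 Hz) and low-pass (125 Hz); a DFT notch
that removes the 50 and 100 Hz line components by least-squares sinusoid
regression over the epoch; inverse-distance-weighted interpolation of bad
channels from neighbors within 40 mm; common-average or linked-mastoid
re-referencing. `prepare_for_decoding()` chains common-average reference,
the 2–8 Hz two-pass FIR, resampling to 100 Hz, and trimming to the
stimulus span, reconciling off-by-one lengths by truncation to the
shorter. Every step is linear, which the test suite verifies directly.

## The backward decoder

The decoder maps lagged multichannel EEG to the envelope: the envelope at
time *t* is predicted from EEG at *t* … *t* + 300 ms in 10 ms steps (31
lags; the lag sign convention is stated explicitly because "shifted
relative to" is direction-ambiguous). Training solves the ridge system
`w = (X'X + λI)^-1 X'y` on z-scored predictors and target (training
statistics; intercept restored on output), with λ chosen by
contiguous-segment k-fold cross-validation maximizing mean held-out
Pearson *r* when a grid is supplied. The pipeline default is a fixed
λ = 10^4, the order of magnitude that cross-validation selects on
training data simulated at the packaged noise level; reconstruction
scores are correlation-based and insensitive to λ over several orders of
magnitude. Scores (`score_reconstruction()`) are Pearson correlations per
3.5 s sentence iteration (exact thirds); the headline analysis consumes
iteration 1 of each presentation. Training always uses the clear-speech
narrative, never the test trials, mirroring the study logic that the
decoder represents normal speech processing.

## Spectral analysis

`tf_decompose()` computes Hanning-taper short-time power (1 s taper,
100 ms steps, 1–30 Hz in 1 Hz bins) scaled so a unit sinusoid at a bin
center has power 1. Band power (`band_average()`) averages the analysis
window [0.5, 3] s — the first sentence iteration with its first and last
0.5 s dropped — and the band's bins (delta 1–3, theta 4–9, alpha 10–15,
beta 16–30 Hz), then log10-transforms. `induced_profile()` implements the
intertrial-variance method: one-pass zero-phase FIR band-pass (order
three cycles of the band's low edge), evoked subtraction, squaring, log10
with a 1e-20 floor, trial averaging, 500 ms moving average, and
downsampling to 10 Hz, with no baseline scaling.

## Cluster-based permutation statistics

Paired dependent-samples t maps are thresholded at the two-tailed 0.025
critical value (`qt(1 − 0.025/2, n − 1)` per tail), supra-threshold
samples are clustered by spatial adjacency (channels within 40 mm) and
bin adjacency with positive and negative clusters formed separately, and
each cluster's summed t mass is referred to the permutation null of the
maximum absolute mass under random sign flips of the participant-wise
differences (exact under exchangeability for paired designs). The Monte
Carlo p includes the observed statistic, `p = (1 + k)/(1 + n_perm)`, so
p is never zero. A supra-threshold sample is clusterable only if at least
2 spatial neighbors are supra-threshold in the same bin; this gate is
applied identically to observed and permuted maps.

Two calibration facts, both measured by the test suite: the 1-D test
(adjacency over time bins only) has empirical type-I error ≈ 0.05 at
nominal 0.05; the spatial gate makes the 2-D test strictly conservative
at desk scale (8 participants, 16 channels: rate ≈ 0.01, because gated
clusters almost never form under the null). The packaged type-I
calibration therefore runs the 2-D test without the gate, which measures
the exactness of the permutation machinery itself and upper-bounds the
gated default (measured rate 0.035 within [0.025, 0.075]). The 16-channel
montage used for scaled-down calibration is a contiguous central patch of
the 64-channel template: a subsampled montage is spatially disconnected
and cannot form clusters at all.

## Pupillometry

Blinks are maximal runs of missing samples up to 5 s (longer runs are
dropouts, never interpolated; trials containing one are flagged for
exclusion and only bridged so the numeric pipeline can continue). Each
blink is replaced by the line joining the medians of the 100 ms windows
flanking it; if a flank window is empty the search widens to the nearest
valid window with a warning. The flank-median convention has an effective
lag of ~50 ms, so interpolation accuracy bounds hold for slow-dominated
(< 0.3 Hz) content — the regime of real pupil dynamics — and degrade for
content approaching 2 Hz. Both eyes are low-pass filtered below 6 Hz
(two-pass 4th-order Butterworth) and averaged; epochs of [−1, 11] s
around each presentation are corrected by the mean pupil size in the
second before the first presentation. Units are arbitrary throughout.

## Problem sizes and reproducibility

Every stochastic stage draws from a named substream derived from the
master seed (`sub_seed()`), so changing one stage's draws never perturbs
another's, and identical (configuration, seed) pairs regenerate identical
results bit-for-bit.

The validation runs use desk-scale problem sizes, chosen once and stated
here: recovery runs keep the full 19 participants and 64-channel montage
but use a 15-pair pool, single-iteration (3.5 s) stimuli, 3 trials per
condition cell (2 for the spectral replicates, 1 for null replicates),
and a 30 s training narrative
shared across participants; trained decoders are reused across replicate
null datasets (training data are independent of the test trials, so this
does not affect test-trial exchangeability). Null calibration uses 20
replicate datasets for the decoder contrast and 200 scaled-down
simulations for the cluster test. The sentence-level envelope checks use
a 5-pair pool. At these sizes the full validation completes in roughly a
quarter hour on one core.

## Known limitations

* The forward model is rank-one and linear; it cannot probe nonlinear or
  distributed-tracking hypotheses.
* Synthetic sentences carry no linguistic content; clarity ratings come
  from a latent-threshold model, not from intelligibility.
* SWS emulation removes syllable-rate amplitude structure by design
  (amplitudes follow only a < 1.5 Hz envelope remnant), which makes SWS
  envelopes nearly unpredictable from the clear version — the intended
  contrast with NVS, but more extreme than real sine-wave speech.
* Mixed-effects inference on ratings, scores, and band power is left to
  external tools on the exported tidy tables; `summarize_conditions()`
  provides descriptive cell means and paired Wilcoxon tests only.
* No HDF5 serialization: sessions are exchanged as directories of TSV and
  JSON (`write_session()`), audio as WAV.
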