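---
title: "Localizing subthalamic DBS contacts from stimulus-evoked EEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing subthalamic DBS contacts from stimulus-evoked EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stnerp)
```

## The problem

Deep brain stimulation (DBS) of the subthalamic nucleus (STN) treats
advanced Parkinson's disease, and its benefit depends on where exactly the
electrode contact sits: in the dorso-lateral motor region (DLR), the
ventro-medial associative-limbic region (VMR), or above the nucleus in the
zona incerta (ZI). `stnerp` implements a non-invasive localization
analysis: stimulate one contact at low frequency (5 Hz for 8 min or 3 Hz
for 13.3 min, 2,400 pulses either way), record 64- or 128-channel scalp
EEG at 1,000 Hz, average the stimulus-locked evoked response potential
(ERP), summarize it with engineered features, and classify the stimulated
region from those features.

The pipeline has five stages, each a package module:

1. **Cleaning** — per-channel DC removal; automatic stimulus-artifact
   detection on the across-channel mean at 3 SD; first-degree (linear)
   interpolation across each detected span; average re-reference; and a
   two-way (zero-phase, forward–backward) windowed-sinc FIR band-pass of
   0.5–40 Hz. 128-channel recordings are interpolated onto the 64-channel
   montage (3-nearest-neighbour inverse-distance weights) first.
2. **ERP extraction** — epochs of −50 to +150 ms around each pulse
   (half-open, 200 samples at 1 kHz), arithmetic trial average with the
   n−1 standard error; optional per-channel z-scoring; reduction of the 64
   channels to nine scalp regions of interest (ROIs).
3. **Engineered features** — for every channel and ROI and each of four
   windows (very early 5–25, early 45–55, middle 50–100, late 100–149 ms):
   max/min peak amplitude, max/min peak latency, peak-to-peak, signed AUC
   and energy — 7 × 4 × (64 + 9) = 2,044 values per session.
4. **Single-feature biomarkers** — pooled-variance independent t-tests
   between region pairs and a cross-validated ROC cutoff model
   (Youden's J) with precision/recall/accuracy/AUC reported as
   mean ± SD over stratified 5-fold CV.
5. **Classification** — minimum-redundancy maximum-relevance (MRMR)
   selection of the top k = 25 features followed by a linear SVM, as three
   two-class contrasts (ZI vs VMR, ZI vs DLR, DLR vs VMR) and a
   three-class one-vs-rest and one-vs-one analysis, with C selected from
   {0.001, 0.01, 0.1, 0.5, 1, 2} by mean CV validation accuracy.

No patient data ship with the package; a synthetic-cohort generator
reproduces the statistical structure the analysis relies on, so every
stage is exercisable and testable end to end.

## The synthetic cohort

`simulation_config()` holds every generative parameter. The defaults are
the study conditions: 5 Hz × 480 s = 2,400 pulses per session, 1,000 Hz
sampling, 64 channels, and a 61-session cohort labelled ZI (20), DLR (23),
VMR (18), with sessions grouped four-per-virtual-patient. A 0.5 s quiet
lead-in/lead-out surrounds the pulse train so every pulse supports a full
epoch.

**Evoked model.** Each (region, ROI) pair carries one Gaussian-windowed
~20 Hz cosine component — a compact stand-in for the "series of
diminishing waves" reported for cortical DBS responses — whose positive
peak lands exactly at the configured latency. Latency defaults encode the
reported group medians: medial fronto-central 77/69/67 ms and right
fronto-central 73.5/62/64 ms for ZI/DLR/VMR, occipital 71 (DLR) and 92 ms
(VMR). The component width is 20 ms, which keeps more than 99.9% of the
template's energy inside the 0.5–40 Hz pass-band, so cleaning does not
materially distort it. ROI templates spread to member channels with weight
1 at the ROI centroid falling to 0.5 at the ROI edge.

**Amplitudes are conventions.** The source measurements are reported in
normalized units, so scalp amplitudes here are free parameters with
documented defaults: 4 µV medial fronto-central, 3 µV right
fronto-central, ~1 µV frontal, 0.08 µV occipito-parietal and 0.05 µV left
frontal (the contralateral null area). The strong fronto-central
concentration mirrors the reported topography, and it matters: were the
occipital response as strong as the fronto-central one, the 21 ms
occipital DLR–VMR latency gap would make the within-STN contrast the
*easiest* classification, inverting the reported ordering. The occipital
default sits at the 2,400-trial ROI noise floor (~0.08 µV), so the
occipital latency remains a weak, noisy cue — detectable, as the single
reported occipital electrode suggests, but not dominant.

**Between-patient variability** enters as one latency shift and one
amplitude gain per session (every ROI shifted together). The shift SD is
region-dependent — 2 ms for ZI and VMR, 6 ms for DLR — rather than a
single pooled value. This is the one place the generator's difficulty is
deliberately calibrated: with a uniform spread, the pairwise latency gaps
(10 ms ZI–VMR medially, 11.5 ms ZI–DLR on the right, 2 ms DLR–VMR) would
order the classification accuracies *against* the reported pattern
(ZI-vs-VMR best, DLR-vs-VMR worst), because the ZI–DLR gap is the largest.
A wider DLR latency distribution is also what the reported test statistics
imply: the ZI–DLR contrast reaches only t ≈ −2.3 on an 11.5 ms gap while
ZI–VMR reaches t ≈ −4 on a 10 ms gap, which is only possible if the DLR
group is substantially more dispersed. Amplitude gain is uniform on
0.8–1.2 for all regions and therefore carries no class information.

**Stimulus artifact.** Each pulse deposits a biphasic transient (one
sample positive, one negative at 1 kHz) of 200 µV — 50× the largest evoked
amplitude — graded linearly from 0.7× to 1.3× across channels so that no
re-referencing trick can cancel it. This guarantees the 3 SD detector
fires at every pulse.

**Background noise** is the sum of three independent filtered-white-noise
streams per channel: a pole-zero "pinking" cascade approximating a 1/f
spectrum (8 µV RMS), a second-order resonator at 10 Hz with 2 Hz bandwidth
(the alpha rhythm, 3 µV RMS), and a flat broadband component (3 µV RMS),
all synthesized at an internal rate of 2 × 55 Hz and linearly upsampled to
1 kHz. Time-domain AR synthesis was chosen deliberately over FFT spectral
shaping: an FFT-synthesized record is periodic, i.e. has a line spectrum,
and those lines resonate with the perfectly periodic 5 Hz pulse train, so
the variance of an N-trial average stops following 1/N at large N. The AR
streams are aperiodic with a continuous spectrum, and the measured RMS of
trial-averaged background follows 1/√N to within ~2% from N = 25 to
N = 1600. The linear upsampling imposes a mild high-frequency droop
(~30% amplitude at 40 Hz) on the nominal spectral shapes; the spectrum
remains monotone-decreasing outside the alpha bump, which is the property
the analysis relies on.

**What the generator does not model.** Volume conduction from a cortical
source model (ROI spread is a geometric convention), antidromic vs
orthodromic pathway structure, amplitude differences between regions,
non-stationary noise (drowsiness, movement), bad channels, and line noise.
Passing tests therefore demonstrate that the *analysis* recovers what this
generative model plants — latencies, topography concentration, region
separability — not that it would perform identically on patient data.

## Numerical and design choices

* **Intervals are half-open, times in ms, events 0-based in samples.**
  The epoch window [−50, 150) gives exactly 200 samples at 1 kHz; feature
  windows are half-open, so the overlapping early/middle windows
  (45–55, 50–100) remain exactly as defined.
* **Artifact detection** runs on the across-channel mean (the DBS pulse is
  scalp-synchronous), with the SD taken over the whole recording; flagged
  runs are extended ±2 ms and merged. Detected spans are replaced by the
  straight line between the last clean sample before and the first after
  (first-degree polynomial fit through the anchors). Spans touching a
  recording edge hold the available anchor and warn.
* **Filtering** uses one windowed-sinc (Hamming) kernel whose length
  follows from a 0.5 Hz transition width (6,601 taps at 1 kHz), applied
  forwards and backwards via FFT convolution (the response is the squared
  magnitude, phase exactly zero). Filtering the linearly interpolated
  artifact spans smears energy slightly before stimulus onset; that
  pre-onset rise is expected and tests never assert pre-stimulus silence.
* **z-scoring** operates per channel over the epoch time course within a
  session; features default to raw (non-z-scored) ERPs with a
  configuration switch (`features_on = "zscore"`).
* **Energy** defaults to the trapezoidal integral of the squared trace
  (conventional signal energy, µV²·ms). The literal reading "square of the
  window integral" is available as `energy_mode = "square_of_integral"`;
  both are exposed because the phrase is ambiguous.
* **Latency ties** resolve to the earliest sample; a zero trace therefore
  reports the window start.
* **t-test** is the pooled-variance Student test (a Welch flag exists).
* **ROC cutoff**: thresholds sweep the unique observed values; the
  orientation is flipped when AUC < 0.5 and recorded; the reported cutoff
  sits at the midpoint of the value gap below the Youden-optimal
  threshold, which generalizes to held-out data (a cutoff placed exactly
  on a training value fails on test points beyond the training extreme).
* **MRMR** uses the mutual-information difference (MID) criterion with
  3-bin equal-frequency discretization computed from average ranks, making
  the ranking invariant to monotone feature transforms and column order; a
  quotient (MIQ) flag exists. By default selection runs inside each
  training fold (no selection leakage); `select_within_folds = FALSE`
  reproduces the alternative of selecting once on the full table, since
  published numbers may reflect either choice.
* **SVM**: features are standardized by training-fold mean/SD (linear SVMs
  on mixed µV/ms units require it); one C per analysis is chosen by mean
  validation accuracy with ties to the smaller C; multiclass precision and
  recall are macro-averaged; folds are stratified and seeded, with class
  remainders assigned to the least-loaded folds so fold sizes stay within
  one of each other.
* **Stability analysis** computes the feature on the first-N-trial average
  over a trial-count grid; the stabilization point is the smallest N from
  which every estimate (including the full-trial one) stays within ±2 ms
  of the full 2,400-trial estimate.
* **Determinism**: every stochastic stage consumes an explicit seed;
  per-session seeds derive from the master seed; equal seeds give
  byte-identical feature tables.

## Problem sizes used by the tests

Unit and property tests run on shortened pulse trains (4–90 s, 20–450
trials) with the same physics as the defaults. The acceptance checks run
the study protocol itself: one full 5 Hz/8 min session for the epoch
count; the full 61-session cohort (the generator's own timing is recorded
per session) for the cohort fixture, latency recovery and classification
ordering; ten full sessions for the trial-count stability analysis; and a
zero-effect cohort for the permutation-null check, which uses 20 s
sessions because chance-level accuracy does not depend on the trial count
once the evoked amplitude is exactly zero.

## Implementation notes

Recordings store their signal time-major (samples × channels) because R is
column-major and the heavy steps — noise synthesis, zero-phase filtering,
epoch gathering — then stream through contiguous memory; a 2,400-trial
64-channel session is ~250 MB as a double tensor, so the per-session
pipeline computes the ERP channel by channel in one pass (a compiled
kernel) instead of materializing the full trial tensor. The modular route
(`extract_epochs()` + `average_epochs()`) is the reference implementation;
a test asserts both routes agree to 1e-10.

## Known limitations

Single-feature p-values are reported raw (the analysis applies no
multiple-testing correction across the 2,044 features, matching the
original procedure); the grouped-by-patient CV mode shares the fold
machinery but the default is stratified-by-class; EDF support covers the
16-bit single-rate profile this pipeline writes, not every EDF+ feature;
and the reported accuracies on synthetic cohorts track the generator's
difficulty settings, not clinical performance.
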