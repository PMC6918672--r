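---
title: "Decoding corticostriatal LFPs: models, nulls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding corticostriatal LFPs: models, nulls, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lfpdecode` asks a single scientific question of multichannel local field
potential (LFP) recordings: *do the band-limited power and coherence
patterns of this circuit carry information about an outcome* — a binary
trait such as biological sex or estrous phase, or a continuous behavior
such as alcohol intake in g/kg? This vignette documents the models, the
parameters that matter, the synthetic-data machinery used to validate the
pipeline, and the design decisions taken where more than one reasonable
choice existed.

## 1. From raw signal to 60 features

### Preprocessing

Recordings are four simultaneous channels (left/right medial prefrontal
cortex, left/right nucleus accumbens shell) in millivolts, nominally at
2 kHz. Four stages run in a fixed order:

1. **Notch.** A Chebyshev type I band-stop of overall order 4 covering
   59–61 Hz removes line noise. The filter is applied forward–backward
   (`signal::filtfilt`), so it is zero-phase: channels stay time-aligned,
   which the coherence estimates require. Passband ripple is 0.25 dB per
   pass (0.5 dB after the two passes); measured attenuation at 60 Hz is
   about 80 dB and the 10-Hz passband deviation is 0.5 dB.
2. **Decimation.** Downsampling by 5 (2 kHz to 400 Hz) behind a 64-tap
   zero-phase FIR low-pass at the post-decimation Nyquist. Without the
   anti-alias filter, 310–330 Hz content would fold onto the 70–90 Hz
   analysis band. A decimation leaving Nyquist at or below 90 Hz — the top
   of the analysis range — is rejected. In-band amplitudes survive to
   within 0.1%.
3. **Artifact exclusion.** Any sample exceeding ±2 mV on *any* channel
   marks an artifact; the excluded interval runs from 12.5 ms before the
   first sample of a contiguous supra-threshold run to 40 s after its last
   sample, and overlapping exclusions merge. The keep-mask is shared by
   all channels. Anchoring the 40-s window at the run's *last* sample is
   the conservative reading (it merges ringing into the artifact);
   applying the threshold after notch and decimation follows the
   processing narrative's order. Both were genuinely open choices.
4. **Epoching.** Every maximal clean interval at least 3 s long is cut
   into consecutive 3-s epochs from its start; remainders are discarded so
   all epochs represent the same amount of data. A clean 30-min session
   yields 600 epochs.

### Spectral estimation

Per epoch and channel, the power spectral density is the average of
Hamming-windowed periodograms over 1.6-s windows with 50% overlap (two
windows per 3-s epoch at 400 Hz; 0.625-Hz bins). The session PSD is the
arithmetic mean of epoch PSDs in linear units. Magnitude-squared coherence
uses 1.3-s windows with 50% overlap (three windows per epoch):
cross- and auto-spectra are averaged over the windows of *all* epochs and
`|Sxy|^2 / (Sxx Syy)` is formed once per session. Pooling at the spectra
level matters: MSC estimated from L windows carries an upward
small-sample bias of order 1/L under independence (about 1/3 for a single
3-window epoch), and averaging per-epoch MSC values across epochs
preserves that bias, whereas pooling spectra across the session's
hundreds of windows drives it to zero. Windows never straddle epoch
boundaries, so the excision joins between non-contiguous clean intervals
contribute no phase discontinuities; a configuration leaving a single
window in total is rejected because MSC from one window is identically 1.
Windows that do not fit are dropped — no zero padding.

### Normalization and the canonical feature vector

Band power is the PSD summed over a band's bins (inclusive edges),
expressed as a percent of the total power over 1–90 Hz with 59–61 Hz
excluded (the notch makes those bins meaningless). Band coherence is the
mean coherence over the band's bins divided by the pair's broadband
(1–90 Hz, minus 59–61 Hz) mean coherence. Both normalizations are ratios,
so all 60 features are invariant to rescaling the signal — gain
differences between headstages cannot masquerade as effects. Percent
normalization is computed in linear power units; decibel scaling is
treated as display only, since percentages of logarithms are not
meaningful.

The feature vector is fixed: 24 power features `pow_<channel>_<band>` in
channel-major order, then 36 coherence features `coh_<chA>-<chB>_<band>`
over the 6 unordered channel pairs in lexicographic order, bands innermost
— 60 names, identical across sessions, so feature matrices are byte-stable
across runs.

One structural consequence of percent normalization worth knowing:
raising one band's power necessarily lowers every other band's *percent*
on that channel. A band holding a large share of total power (delta or
theta, typically 30–50%) therefore drags the other features along with
shifts of comparable magnitude; a band with a small share (low gamma,
a few percent) perturbs the rest negligibly. The recovery demonstrations
below target low gamma for exactly this reason.

## 2. Decoding and inference

### Cross-validated lasso

The decoder is an L1-penalized (lasso) linear or logistic regression
(`glmnet`), under `n_folds = 4` outer folds repeated
`n_repetitions = 100` times (10 at desk scale). Outer folds are
stratified by class for binary tasks. Within each outer training portion,
the penalty is chosen by 3-fold inner cross-validation over a 50-point
penalty path, minimum-deviance rule (`lambda.min`); features are
standardized on training data only. Each repetition's metric pools that
repetition's held-out predictions: percent correct at a 0.5 probability
threshold (binary; pooling rather than per-fold averaging matters when
fold sizes differ), or mean squared error in (g/kg)² (continuous; MSE is
the gaussian lasso's native deviance — the field reports "error" without
naming a metric, so the definition is stated here once). Means, SEM, SD
and percentile 95% CIs summarize the repetition distribution; both SEM
and SD are reported because published "± x" values are ambiguous between
the two.

Cross-validation is *sample-level*: multiple recordings of one animal are
treated as separate samples, and can land in different folds. That is a
deliberate mirror of the experimental design this pipeline serves — and
it is exactly the leak that the group-permutation null (below) is built
to quantify. A rat-grouped fold option was considered and rejected for
v1: the group permutation answers the same question without changing the
primary analysis.

### Two nulls

- **Random permutation** (default 100 permutations): outcomes shuffled
  across all rows; every link between features and outcome is broken.
  This estimates chance.
- **Group permutation**: whole rats — with all their recordings — are
  reassigned to *labeled* pseudo-groups of the original sizes, with a
  balance covariate (e.g. sex) equally represented in each pseudo-group.
  All balanced assignments are enumerated when there are at most
  `group_enumeration_cap` of them (4+4 rats balanced 2+2: C(4,2)² = 36,
  minus the true assignment = 35 candidates); above the cap, candidates
  are sampled uniformly without replacement. The true assignment is
  excluded — including it would bias the null toward the real statistic.
  Because genuine rat-to-rat differences survive this shuffle, a
  group-permutation distribution that matches the real model's accuracy
  says the model is reading *animal identity*, not the outcome.

Null model fits default to 10 CV repetitions rather than the real model's
100: each null point is already an average, and the null summarizes
means, not per-repetition spread.

Comparisons report `z = (real − null mean) / null SD` (sign flipped for
error metrics so better-than-null is always positive) and the add-one
empirical p-value `(1 + #{null at least as good}) / (1 + n_perms)`. The
z-score uses the null SD, not its SEM — published z values of order 1–2
alongside double-digit accuracy gaps are only consistent with a
spread-based denominator.

### Single-feature ranking

Binary: each feature alone in a logistic regression, evaluated under the
same repeated stratified CV, scored by mean AUC over repetitions
(cross-validated, since a published "mean AUC" implies an average over
something); direction is taken from raw group means, which is
threshold-free. Continuous: ordinary least squares per feature on all
rows, reporting in-sample R² and slope (no CV qualifier is attached to
published single-feature R² values). AUC and direction are invariant to
monotone transforms of a feature; ranking ties break by canonical feature
order so tables are deterministic.

## 3. The synthetic cohort generator

Because no public recordings exist for this circuit/protocol, the
generator is a first-class, tested module rather than a fixture. Each
channel is a sum of: six independent band-limited Gaussian components
(white noise spectrally shaped to each canonical band, exact RMS);
optional shared latent band-limited sources on linked channel pairs
(`x = w·s + sqrt(1−w²)·private`), which induce coherence with a
closed-form magnitude-squared coherence oracle under linear mixing;
1/f-shaped background noise (so spectra look realistic and normalization
denominators are never zero); and optional rectangular artifact pulses
for exercising the ±2 mV rule. Intake outcomes are sparse linear
functions of named features plus Gaussian noise, clipped at zero g/kg.

Structure across animals: each rat draws one multiplicative log-normal
amplitude offset per channel × band (`rat_random_effect_sd`, default 0.1),
each session draws an additional jitter (`session_jitter_sd`, default
0.05), and a group effect multiplies the target channel/band amplitude in
group 2.

**Effect-size calibration.** Group effects are specified in units of the
*extracted feature's* within-group SD, because that is the scale on which
classifiers and rankings operate. The mapping from an amplitude
multiplier to a feature shift is not transparent — percent normalization
dampens it by the band's power share, the in-band 1/f floor dilutes it,
and spectral-estimation noise widens the within-group SD — so the
generator calibrates empirically: it simulates a no-effect pilot cohort
(8 rats × 3 sessions with the same random-effect structure), measures the
target feature's within-group coefficient of variation and power share,
solves for the multiplier (accounting for the shifted group's
proportionally inflated SD, i.e. a pooled-SD effect-size convention), and
then verifies against a second pilot with the candidate multiplier
applied, correcting any residual dilution. Across seeds, a nominal 3-SD
effect realizes a raw-scale Cohen's d within ~15% of 3. A cheaper
`generating_sd` scale (multiplier `exp(d·σ)` on log-amplitude, no pilots)
remains available when only a monotone handle is needed.

**Default conditions.** Session defaults mirror the experimental
protocol: 2 kHz, 30 min, band amplitudes 0.10/0.08/0.05/0.04/0.025/0.02
mV RMS (delta through high gamma) over a 0.05 mV 1/f background — chosen
for realistic-looking spectra and convenient SNR, as no published
spectral parameters exist for this preparation. Desk-scale validation
cohorts (tests and the acceptance script) use 90-s sessions generated
directly at the 400-Hz analysis rate with `downsample_factor = 1`: the
2 kHz → 400 Hz decimation contract is exercised separately on 2-kHz
sessions, and generating at the analysis rate keeps a 20-seed study
inside minutes of CPU rather than hours. Recovery demonstrations use
4 rats/group × 2 recordings with `rat_random_effect_sd = 0` — the
recovery question is whether the *group* effect is found, and the
rat-effect confound gets its own demonstration with strong rat effects
(SD 0.6) and arbitrary labels, where the group-permutation null's mean
accuracy matches the real model's within one null SD.

**What the simulator does not emulate:** neural-mass dynamics,
nonstationarity within sessions, behavioral structure in time,
cross-frequency coupling, or volume conduction. Passing recovery tests
shows the *pipeline* is sound — that effects put in are found, and
absent effects are not — not that real corticostriatal data behave like
the simulator.

## 4. Numerical choices and degenerate inputs

- Band membership and the 59–61 Hz exclusion use inclusive bin edges on
  each spectrum's native grid (0.625 Hz for PSDs, ~0.769 Hz for
  coherence).
- Zero total power (degenerate signal) and zero broadband coherence are
  errors, not NaNs; empty epoch sets warn at segmentation and error at
  feature extraction.
- Constant features rank with AUC 0.5 / R² 0 and a `constant` flag;
  constant outcomes are rejected.
- Null SD of zero leaves the z-score undefined (`NA`) while the count
  rule still yields an empirical p.
- All randomness flows through explicit integer seeds; fold assignments
  are pure functions of `(seed, repetition)`, and identical seeds
  reproduce cohorts, fits, and null distributions bit-for-bit.
- Intervals are half-open in time, sample indices are 0-based in
  time arithmetic (sample *i* sits at *(i−1)/fs* seconds in R's 1-based
  indexing).

## 5. Interfaces

Everything is driven from R: simulators, preprocessing, feature
extraction, models, nulls, and rankings are plain functions, and
`run_pipeline()` composes them under a single-seed `pipeline_config()`
that serializes to YAML (unknown keys are rejected so typos cannot
silently become defaults). Cohorts serialize to one little-endian float32
binary per session (channel-major) with a JSON sidecar and a manifest
CSV; the feature matrix CSV — metadata columns then the 60 canonical
features — is the stable interchange point between the signal half and
the statistics half, so users with their own preprocessed features can
enter at the modeling stage. No shell entry point is provided: the
intended users drive analyses from R scripts, and a CLI wrapper over
these functions would add surface without capability.

## 6. Known limitations

- Only the fixed 4-channel montage is tested; channel lists are constants
  of the canonical ordering, not a general montage system.
- One notch at 60 Hz: harmonics (120, 180 Hz) are outside the 1–90 Hz
  analysis range post-decimation and are not separately filtered.
- Sample-level CV inflates accuracy when animals are individually
  distinctive; use the group-permutation null to measure that inflation
  rather than reading accuracies at face value.
- Welch windows overlap, so the effective degrees of freedom behind each
  PSD bin are slightly below the window count; the effect-size
  calibration absorbs this empirically rather than modeling it.
- The continuous single-feature R² is in-sample and optimistic at small
  n (E[R²] ≈ 1/(n−1) under independence).
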