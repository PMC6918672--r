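# lfpdecode

Decoding biological outcomes from corticostriatal local field potentials
(LFPs) in rodents.

## The problem

Local field potentials recorded simultaneously from the bilateral medial
prefrontal cortex (mPFC) and nucleus accumbens shell (NAcSh) carry
oscillatory structure — delta (1–4 Hz), theta (5–10 Hz), alpha (11–14 Hz),
beta (15–30 Hz), low gamma (45–65 Hz) and high gamma (70–90 Hz) — whose
band power and between-region coherence may encode trait-level variables
(biological sex, estrous phase) and behavioral ones (alcohol intake in
g/kg). `lfpdecode` implements the full analysis chain for asking whether
that information is really there:

1. **Preprocessing** — 60-Hz Chebyshev type I notch (order 4, zero-phase),
   decimation from 2 kHz to 400 Hz behind a zero-phase anti-alias FIR,
   ±2 mV amplitude-threshold artifact exclusion (12.5 ms before to 40 s
   after each artifact run, merged), and segmentation of the surviving data
   into channel-aligned 3-s epochs.
2. **Spectral features** — Welch power spectral densities (1.6-s Hamming
   windows, 50% overlap) and magnitude-squared coherence (1.3-s windows,
   50% overlap), averaged across epochs, reduced to the canonical
   **60-feature vector**: 24 band powers (6 bands × 4 channels, each a
   percent of the 1–90 Hz total, 59–61 Hz excluded) and 36 band coherences
   (6 bands × 6 channel pairs, each normalized by the pair's broadband mean
   coherence).
3. **Decoding** — lasso (L1-penalized) regression under fourfold
   cross-validation repeated 100 times, with the penalty chosen by inner
   cross-validation on each training fold. Binary outcomes are scored by
   held-out accuracy (%), continuous ones by held-out mean squared error.
4. **Permutation inference** — the real model is compared against a
   *random-permutation* null (outcomes shuffled across all recordings;
   chance level) and a *group-permutation* null (whole animals reassigned
   to balanced pseudo-groups, keeping each rat's recordings together;
   information about arbitrary animal groupings), summarized by z-scores
   and add-one empirical p-values.
5. **Ranking** — exhaustive single-feature models: cross-validated mean
   AUC (binary) or in-sample R² and slope (continuous) for each of the 60
   features.
6. **Synthetic cohorts** — a simulator with band-structured spectra,
   controllable inter-channel coherence (shared latent sources), 1/f
   background, injectable artifacts, per-rat random effects, and
   calibrated group effects in within-group SD units, so every stage can
   be validated against known ground truth without any recordings.

## Worked example

Simulate a small cohort in which female rats carry a 3-SD elevation of
left-NAcSh low-gamma power, extract features, decode sex, and compare with
a permutation null:

```r
library(lfpdecode)

cs <- cohort_spec(
  n_rats_per_group = 4, recordings_per_rat = 2,
  group_effect = data.frame(channel = "L_NAcSh", band = "low_gamma",
                            effect_size = 3),
  rat_random_effect_sd = 0,
  base_spec = simulation_spec(fs_hz = 400, duration_s = 90),
  seed = 1)
cohort <- simulate_cohort(cs)
fm <- extract_feature_matrix(cohort$sessions,
                             preprocess_config(downsample_factor = 1))

x <- feature_columns(fm)                      # 16 sessions x 60 features
y <- factor(fm$sex, levels = c("male", "female"))
cvc <- cv_config(n_repetitions = 10, task = "binary", seed = 1)

real <- fit_lasso_cv(x, y, cvc)
null <- random_permutation_null(x, y, cvc,
         permutation_config(n_random_perms = 50, null_repetitions = 10,
                            seed = 1))
compare_to_null(real, null)
#> <random permutation null> 50 permutations: mean 49.325, SD 3.775 [95% CI 43.750, 57.359]
#>   real mean 96.875, z = 12.60, empirical p = 0.0196

head(single_feature_classification(x, y, cvc), 3)
#>                         feature  mean_auc     direction constant
#> 1         pow_L_NAcSh_low_gamma 0.9937500 female > male    FALSE
#> 2 coh_L_mPFC-L_NAcSh_high_gamma 0.8468750 female > male    FALSE
#> 3             pow_L_NAcSh_theta 0.8179688 male > female    FALSE
```

The real model decodes sex at 96.9% held-out accuracy while
label-shuffled nulls sit at chance (49.3%), z = 12.6, empirical
p = 1/51 ≈ 0.02, and the planted feature tops the AUC ranking at 0.994 —
the pipeline recovers exactly the effect that was simulated. (Numbers
vary slightly with seeds; the ones above are from the configuration
shown.)

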