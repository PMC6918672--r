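# Shared fixtures: all data are generated in code at test time.

# Cut a channels x samples matrix into consecutive 3-s epochs, bypassing
# preprocessing (for tests that target the spectral stage directly).
epochs_from_signal <- function(sig, fs_hz, epoch_len_s = 3, ref = "fix") {
  seg <- round(epoch_len_s * fs_hz)
  n_seg <- ncol(sig) %/% seg
  eps <- lapply(seq_len(n_seg), function(k)
    sig[, ((k - 1) * seg + 1):(k * seg), drop = FALSE])
  lfp_epochs(eps, fs_hz, ref, epoch_len_s)
}

# 4-channel matrix of sinusoids (one frequency per channel) plus faint noise
# so normalization denominators are never zero.
sine_signal <- function(freqs, fs_hz, duration_s, amp = 0.5,
                        noise = 1e-3, seed = 42) {
  t <- seq(0, duration_s - 1 / fs_hz, by = 1 / fs_hz)
  with_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); expr
  }
  with_seed(seed, {
    sig <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t),
                    numeric(length(t))))
    sig + matrix(rnorm(length(sig), 0, noise), nrow = nrow(sig))
  })
}

# Desk-scale cohort for the statistics half: sessions generated directly at
# the 400 Hz analysis rate (no decimation needed), 90 s long.
desk_cohort <- function(seed, effect_size = 0, n_rats = 4, recordings = 2,
                        rat_sd = 0, target_channel = "L_NAcSh",
                        target_band = "low_gamma") {
  cohort_spec(
    n_rats_per_group = n_rats, recordings_per_rat = recordings,
    group_effect = if (effect_size != 0)
      data.frame(channel = target_channel, band = target_band,
                 effect_size = effect_size) else NULL,
    rat_random_effect_sd = rat_sd,
    base_spec = simulation_spec(fs_hz = 400, duration_s = 90),
    seed = seed)
}

desk_features <- function(cohort) {
  sim <- simulate_cohort(cohort)
  fm <- extract_feature_matrix(sim$sessions,
                               preprocess_config(downsample_factor = 1))
  fm
}

# glmnet emits small-class warnings at desk-scale n; they are expected.
fit_quiet <- function(...) suppressWarnings(fit_lasso_cv(...))
rank_quiet <- function(...) suppressWarnings(single_feature_classification(...))
null_quiet <- function(...) suppressWarnings(random_permutation_null(...))
gnull_quiet <- function(...) suppressWarnings(group_permutation_null(...))
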