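test_that("band-limited noise hits its RMS and stays in band", {
  expect_identical(band_limited_noise("theta", 1, 400, 0), numeric(400))
  x <- band_limited_noise("theta", 60, 2000, 0.1, seed = 3)
  expect_equal(sqrt(mean(x^2)), 0.1, tolerance = 0.05)
  expect_lt(abs(mean(x)), 1e-12)
  # oracle: direct periodogram integration of the output
  pg <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * 2000 / length(x)
  half <- f <= 1000
  in_band <- sum(pg[half & f >= 5 & f <= 10]) / sum(pg[half])
  expect_gt(in_band, 0.9)
  expect_identical(band_limited_noise("theta", 2, 400, 0.1, seed = 9),
                   band_limited_noise("theta", 2, 400, 0.1, seed = 9))
  expect_error(band_limited_noise("high_gamma", 1, 150, 0.1), "Nyquist")
})

test_that("pink noise has the requested RMS and 1/f-falling spectrum", {
  x <- pink_noise(30, 400, 0.05, seed = 5)
  expect_equal(sqrt(mean(x^2)), 0.05, tolerance = 1e-10)
  pg <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * 400 / length(x)
  low <- sum(pg[f >= 1 & f <= 10])
  high <- sum(pg[f >= 40 & f <= 49])
  expect_gt(low, high)
})

test_that("artifact injection produces detectable threshold crossings", {
  sig <- matrix(0, 4, 400 * 10)
  one <- inject_artifacts(sig, 400, data.frame(time_s = 2, amplitude_mv = 3,
                                               width_s = 0.05))
  expect_false(all(artifact_mask(one, 400)))
  small <- inject_artifacts(sig, 400, data.frame(time_s = 2,
                                                 amplitude_mv = 1,
                                                 width_s = 0.05))
  expect_true(all(artifact_mask(small, 400)))
  two <- inject_artifacts(sig, 400, data.frame(time_s = c(1, 5),
                                               amplitude_mv = 3,
                                               width_s = 0.05))
  # brute-force scan: count runs of supra-threshold samples
  supra <- apply(abs(two) > 2, 2, any)
  runs <- rle(supra)
  expect_identical(sum(runs$values), 2L)
  expect_error(
    inject_artifacts(sig, 400, data.frame(time_s = 11, amplitude_mv = 3,
                                          width_s = 0.05)),
    "outside")
})

test_that("simulated sessions have the right shape and controllable spectra", {
  s <- simulate_session(simulation_spec(duration_s = 6, seed = 7),
                        "r1", "male")
  expect_identical(dim(s$signal), c(4L, 12000L))
  # doubling theta amplitude on one channel shows up in the extracted power
  amps <- default_band_amplitudes()
  amps["L_NAcSh", "theta"] <- 2 * amps["R_NAcSh", "theta"]
  spec <- simulation_spec(fs_hz = 400, duration_s = 60,
                          band_amplitudes = amps, seed = 21)
  ep <- preprocess_session(simulate_session(spec, "r1", "male"),
                           preprocess_config(downsample_factor = 1))
  v <- extract_features(ep)
  expect_gt(v[["pow_L_NAcSh_theta"]], v[["pow_R_NAcSh_theta"]])
})

test_that("coherence links induce band-specific coherence", {
  links <- data.frame(chan_a = "L_mPFC", chan_b = "L_NAcSh",
                      band = "low_gamma", weight = 0.9)
  spec <- simulation_spec(fs_hz = 400, duration_s = 120,
                          coherence_links = links, seed = 13)
  ep <- preprocess_session(simulate_session(spec, "r1", "male"),
                           preprocess_config(downsample_factor = 1))
  v <- extract_features(ep)
  expect_gt(v[["coh_L_mPFC-L_NAcSh_low_gamma"]],
            v[["coh_L_mPFC-L_NAcSh_delta"]])
})

test_that("cohort generation is counted, balanced, and deterministic", {
  cs <- cohort_spec(n_rats_per_group = 5, recordings_per_rat = 5,
                    base_spec = simulation_spec(duration_s = 3, seed = 1),
                    seed = 2)
  co <- simulate_cohort(cs)
  expect_length(co$sessions, 50)
  expect_identical(nrow(co$manifest), 50L)
  expect_identical(as.vector(table(co$manifest$sex)), c(25L, 25L))
  expect_identical(length(unique(co$manifest$rat_id)), 10L)
  # males never carry an estrous phase
  expect_true(all(co$manifest$estrous_phase[co$manifest$sex == "male"] ==
                    "not_applicable"))
  co2 <- simulate_cohort(cs)
  expect_identical(co$sessions[[7]]$signal, co2$sessions[[7]]$signal)
})

test_that("intake outcomes follow the generating weights", {
  fm <- data.frame(matrix(rnorm(10 * 60), 10, 60))
  colnames(fm) <- lfp_feature_names()
  w <- c(pow_L_NAcSh_theta = -2)
  out <- simulate_intake_outcomes(fm, w, noise_sd = 0, intercept = 50)
  expect_equal(out$intake, pmax(0, 50 - 2 * fm$pow_L_NAcSh_theta))
  # noiseless outcome -> perfect single-feature regression
  rk <- single_feature_regression(feature_columns(fm), out$intake)
  expect_identical(rk$feature[1], "pow_L_NAcSh_theta")
  expect_equal(rk$r_squared[1], 1, tolerance = 1e-9)
  expect_error(simulate_intake_outcomes(fm, c(nope = 1)), "unknown feature")
})
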