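fsd <- 400

test_that("Welch PSD localizes a sinusoid to within one bin", {
  t3 <- seq(0, 3 - 1 / fsd, by = 1 / fsd)
  sp <- welch_psd(sin(2 * pi * 8 * t3), fsd)
  expect_equal(diff(sp$freq)[1], 0.625)
  expect_lt(abs(sp$freq[which.max(sp$values)] - 8), 0.625 + 1e-9)
  expect_identical(welch_psd(numeric(1200), fsd)$values, numeric(321))
  expect_error(welch_psd(numeric(100), fsd), "shorter than")
})

test_that("integrated Welch PSD matches signal variance (Parseval oracle)", {
  set.seed(4)
  acc <- 0
  n_ep <- 100
  for (i in seq_len(n_ep)) {
    x <- rnorm(1200)
    sp <- welch_psd(x, fsd)
    acc <- acc + sum(sp$values) * diff(sp$freq)[1]
  }
  expect_equal(acc / n_ep, 1, tolerance = 0.1)
})

test_that("session PSD is the arithmetic mean of epoch PSDs", {
  set.seed(5)
  base <- matrix(rnorm(4 * 1200, 0, 0.1), 4, 1200)
  same <- epochs_from_signal(cbind(base, base), fsd)
  sp1 <- welch_psd(base[1, ], fsd)
  expect_equal(session_psd(same, 1)$values, sp1$values)
  # epochs with per-bin power p and 3p average to 2p
  mixed <- lfp_epochs(list(base, sqrt(3) * base), fsd)
  expect_equal(session_psd(mixed, 1)$values, 2 * sp1$values)
  # order does not matter
  flipped <- lfp_epochs(list(sqrt(3) * base, base), fsd)
  expect_equal(session_psd(mixed, 1)$values, session_psd(flipped, 1)$values)
  expect_error(session_psd(lfp_epochs(list(), fsd), 1), "empty")
})

test_that("coherence is 1 for identical channels and small for independent ones", {
  set.seed(6)
  x <- rnorm(1200)
  msc <- msq_coherence(x, x, fsd)
  expect_true(all(abs(msc$values - 1) < 1e-8))
  expect_equal(diff(msc$freq)[1], fsd / 520)
  # independent white noise, 200 epochs pooled at the spectra level: the
  # session estimator's bias vanishes with the total window count
  sig <- matrix(rnorm(4 * 1200 * 200), 4)
  ep <- epochs_from_signal(sig, fsd)
  sc <- session_coherence(ep, 1, 2)
  expect_lt(mean(sc$values), 0.2)
  # whereas a single epoch's 3-window MSC carries ~1/3 upward bias
  one <- msq_coherence(sig[1, 1:1200], sig[2, 1:1200], fsd)
  expect_gt(mean(one$values), 0.2)
  # a single-window configuration is uninformative and must be rejected
  expect_error(msq_coherence(x, x, fsd, spectral_config(coh_window_s = 3)),
               "at least 2 windows")
})

test_that("coherence of linearly mixed signals matches the closed form", {
  # x = s + n1, y = a*s + n2, all white: MSC is flat at
  # a^2 S^2 / ((S + N1) (a^2 S + N2))
  set.seed(7)
  a <- 0.8
  s_sd <- 1; n1_sd <- 0.7; n2_sd <- 0.5
  n_ep <- 200
  s <- rnorm(1200 * n_ep, 0, s_sd)
  sig <- rbind(s + rnorm(1200 * n_ep, 0, n1_sd),
               a * s + rnorm(1200 * n_ep, 0, n2_sd),
               rnorm(1200 * n_ep, 0, 1e-3),
               rnorm(1200 * n_ep, 0, 1e-3))
  sc <- session_coherence(epochs_from_signal(sig, fsd), 1, 2)
  S <- s_sd^2; N1 <- n1_sd^2; N2 <- n2_sd^2
  expected <- a^2 * S^2 / ((S + N1) * (a^2 * S + N2))
  measured <- mean(sc$values[sc$freq >= 5 & sc$freq <= 150])
  expect_lt(abs(measured - expected), 0.1)
})

test_that("band power features follow bin counting on a flat spectrum", {
  freq <- seq(0, 200, by = 0.625)
  flat <- structure(list(freq = freq, values = rep(1, length(freq)),
                         kind = "psd"), class = "lfp_spectrum")
  psds <- stats::setNames(rep(list(flat), 4), lfp_channels())
  v <- band_power_features(psds)
  cfg <- spectral_config()
  total_bins <- sum(freq >= 1 & freq <= 90 & !(freq >= 59 & freq <= 61))
  b <- lfp_bands()
  for (i in seq_len(nrow(b))) {
    n_band <- sum(freq >= b$low_hz[i] & freq <= b$high_hz[i])
    expect_lt(abs(v[[paste0("pow_L_mPFC_", b$name[i])]] -
                    100 * n_band / total_bins), 1)
  }
  expect_true(all(v >= 0))
  # bands do not tile 1-90 Hz, so the per-channel sum stays below 100
  expect_lt(sum(v[grep("L_mPFC", names(v))]), 100)
})

test_that("a pure in-band tone concentrates its band power feature", {
  sig <- sine_signal(c(8, 8, 8, 8), fsd, 30, amp = 0.5, noise = 1e-4)
  ep <- epochs_from_signal(sig, fsd)
  psds <- lapply(stats::setNames(lfp_channels(), lfp_channels()),
                 function(ch) session_psd(ep, ch))
  v <- band_power_features(psds)
  expect_gt(v[["pow_L_mPFC_theta"]], 95)
  others <- v[grep("L_mPFC", names(v))]
  expect_lt(sum(others) - others[["pow_L_mPFC_theta"]], 5)
})

test_that("band coherence features are ratios to the broadband mean", {
  freq <- seq(0, 200, by = fsd / 520)
  const <- structure(list(freq = freq, values = rep(0.4, length(freq)),
                          kind = "coherence"), class = "lfp_spectrum")
  pairs <- lfp_channel_pairs()
  keys <- paste0(pairs[, 1], "-", pairs[, 2])
  cohs <- stats::setNames(rep(list(const), 6), keys)
  v <- band_coherence_features(cohs)
  expect_equal(unname(v), rep(1, 36), tolerance = 1e-12)
  # elevation confined to low gamma raises that ratio above 1 and pushes
  # the out-of-band ratios below 1
  vals <- rep(0.2, length(freq))
  vals[freq >= 45 & freq <= 65] <- 0.8
  bump <- structure(list(freq = freq, values = vals, kind = "coherence"),
                    class = "lfp_spectrum")
  cohs[[keys[1]]] <- bump
  v2 <- band_coherence_features(cohs)
  expect_gt(v2[[paste0("coh_", keys[1], "_low_gamma")]], 1)
  expect_lt(v2[[paste0("coh_", keys[1], "_delta")]], 1)
  expect_true(all(v2 >= 0))
})

test_that("the 60-feature vector is canonical, deterministic, and scale-free", {
  set.seed(11)
  sig <- matrix(rnorm(4 * fsd * 12, 0, 0.3), 4, fsd * 12) +
    sine_signal(c(4, 8, 20, 55), fsd, 12, amp = 0.2)
  ep <- epochs_from_signal(sig, fsd)
  v <- extract_features(ep)
  expect_identical(names(v), lfp_feature_names())
  expect_true(all(v[1:24] >= 0 & v[1:24] <= 100))
  expect_true(all(v[25:60] >= 0))
  expect_identical(v, extract_features(ep))
  # both normalizations are ratios: global rescaling changes nothing
  v_scaled <- extract_features(epochs_from_signal(5 * sig, fsd))
  expect_equal(v, v_scaled, tolerance = 1e-10)
})

test_that("relabeling left/right channels permutes values but not name order", {
  set.seed(12)
  sig <- matrix(rnorm(4 * fsd * 12, 0, 0.3), 4, fsd * 12) +
    sine_signal(c(4, 8, 20, 55), fsd, 12, amp = 0.3)
  v <- extract_features(epochs_from_signal(sig, fsd))
  swapped <- sig[c(2, 1, 4, 3), ]
  v_sw <- extract_features(epochs_from_signal(swapped, fsd))
  expect_identical(names(v_sw), lfp_feature_names())
  b <- lfp_bands()$name
  expect_equal(unname(v_sw[paste0("pow_L_mPFC_", b)]),
               unname(v[paste0("pow_R_mPFC_", b)]))
  expect_equal(unname(v_sw[paste0("pow_L_NAcSh_", b)]),
               unname(v[paste0("pow_R_NAcSh_", b)]))
  # the L-L pair becomes the R-R pair under the swap
  expect_equal(unname(v_sw[paste0("coh_L_mPFC-L_NAcSh_", b)]),
               unname(v[paste0("coh_R_mPFC-R_NAcSh_", b)]))
})
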