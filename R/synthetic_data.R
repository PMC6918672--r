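# Cohort and session simulator: band-structured oscillations with controllable
# inter-channel coherence, 1/f background, artifacts, and per-rat random
# effects, so downstream stages can be validated against known ground truth.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

resolve_band <- function(band) {
  bands <- lfp_bands()
  if (is.character(band) && length(band) == 1L) {
    i <- match(band, bands$name)
    if (is.na(i)) stop("unknown band: ", band, call. = FALSE)
    c(bands$low_hz[i], bands$high_hz[i])
  } else if (is.numeric(band) && length(band) == 2L && band[1] < band[2]) {
    as.numeric(band)
  } else {
    stop("`band` must be a band name or c(low_hz, high_hz)", call. = FALSE)
  }
}

#' Band-limited Gaussian noise
#'
#' Synthesizes a zero-mean random trace whose spectral power is confined to a
#' frequency band, by spectral shaping: white Gaussian noise is transformed to
#' the frequency domain, bins outside the band are zeroed (flat in-band,
#' randomized phases), and the result is rescaled to the requested RMS.
#'
#' @param band A canonical band name (see [lfp_bands()]) or `c(low_hz, high_hz)`.
#' @param duration_s Duration in seconds (> 0).
#' @param fs_hz Sampling rate in Hz; must exceed twice the band's upper edge.
#' @param rms_mv Target root-mean-square amplitude in millivolts (>= 0).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return Numeric vector of `round(duration_s * fs_hz)` samples.
#' @examples
#' x <- band_limited_noise("theta", 10, 400, 0.1, seed = 1)
#' sqrt(mean(x^2))
#' @export
band_limited_noise <- function(band, duration_s, fs_hz, rms_mv, seed = NULL) {
  lim <- resolve_band(band)
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (fs_hz <= 2 * lim[2])
    stop(sprintf(
      "sampling rate %g Hz violates Nyquist for band upper edge %g Hz (need fs > %g Hz)",
      fs_hz, lim[2], 2 * lim[2]), call. = FALSE)
  if (rms_mv < 0) stop("`rms_mv` must be nonnegative", call. = FALSE)
  n <- round(duration_s * fs_hz)
  if (rms_mv == 0) return(numeric(n))
  with_seed(seed, shaped_noise(n, fs_hz, rms_mv, function(f) {
    as.numeric(f >= lim[1] & f <= lim[2])
  }))
}

#' 1/f (pink) background noise
#'
#' Background trace with power spectral density proportional to 1/f across
#' the analyzed range, giving realistic broadband spectra so normalization
#' denominators are never zero.
#'
#' @inheritParams band_limited_noise
#' @return Numeric vector of `round(duration_s * fs_hz)` samples.
#' @export
pink_noise <- function(duration_s, fs_hz, rms_mv, seed = NULL) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (rms_mv < 0) stop("`rms_mv` must be nonnegative", call. = FALSE)
  n <- round(duration_s * fs_hz)
  if (rms_mv == 0) return(numeric(n))
  with_seed(seed, shaped_noise(n, fs_hz, rms_mv, function(f) {
    ifelse(f > 0, 1 / sqrt(f), 0)
  }))
}

# White Gaussian noise spectrally shaped by amplitude gain `gain_fn(freq)`,
# DC removed, rescaled to exact target RMS.
shaped_noise <- function(n, fs_hz, rms_mv, gain_fn) {
  x <- stats::rnorm(n)
  spec <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs_hz / n
  f <- pmin(f, fs_hz - f)  # two-sided frequency magnitude
  g <- gain_fn(f)
  g[1] <- 0  # zero mean
  y <- Re(stats::fft(spec * g, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r == 0) stop("shaping gain annihilated the signal (empty band?)", call. = FALSE)
  y * (rms_mv / r)
}

default_band_amplitudes <- function() {
  m <- matrix(rep(c(0.10, 0.08, 0.05, 0.04, 0.025, 0.02),
                  each = length(lfp_channels())),
              nrow = length(lfp_channels()),
              dimnames = list(lfp_channels(), lfp_bands()$name))
  m
}

#' Specify one simulated recording session
#'
#' @param fs_hz Sampling rate (default 2000 Hz, matching the acquisition rate
#'   the pipeline expects).
#' @param duration_s Session length in seconds (default 1800, a 30-min session).
#' @param band_amplitudes 4 x 6 matrix (channels x bands) of per-component RMS
#'   amplitudes in mV. Default amplitudes fall off with frequency over a 1/f
#'   background.
#' @param coherence_links Data frame with columns `chan_a`, `chan_b`, `band`,
#'   `weight` (mixing weight in \[0, 1\]). Each linked pair shares a latent
#'   band-limited source: both channels' band component is
#'   `weight * shared + sqrt(1 - weight^2) * private`, inducing coherence in
#'   that band only. A channel may appear in at most one link per band.
#' @param pink_noise_rms RMS (mV) of the per-channel 1/f background.
#' @param artifacts Data frame with columns `time_s`, `amplitude_mv`,
#'   `width_s` and optionally `channel` (index, default 1): rectangular pulses
#'   added to the signal, for exercising artifact rejection.
#' @param seed Integer seed making the session reproducible.
#' @return An object of class `lfp_sim_spec`.
#' @export
simulation_spec <- function(fs_hz = 2000, duration_s = 1800,
                            band_amplitudes = default_band_amplitudes(),
                            coherence_links = NULL,
                            pink_noise_rms = 0.05,
                            artifacts = NULL,
                            seed = 1L) {
  stopifnot(fs_hz > 0, duration_s > 0, pink_noise_rms >= 0)
  if (!is.matrix(band_amplitudes) ||
      !identical(dim(band_amplitudes),
                 c(length(lfp_channels()), nrow(lfp_bands()))))
    stop("`band_amplitudes` must be a 4 x 6 channels x bands matrix",
         call. = FALSE)
  if (any(band_amplitudes < 0)) stop("amplitudes must be nonnegative", call. = FALSE)
  dimnames(band_amplitudes) <- list(lfp_channels(), lfp_bands()$name)
  if (!is.null(coherence_links)) {
    need <- c("chan_a", "chan_b", "band", "weight")
    if (!all(need %in% names(coherence_links)))
      stop("`coherence_links` needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (!all(coherence_links$chan_a %in% lfp_channels()) ||
        !all(coherence_links$chan_b %in% lfp_channels()))
      stop("unknown channel in `coherence_links`", call. = FALSE)
    if (!all(coherence_links$band %in% lfp_bands()$name))
      stop("unknown band in `coherence_links`", call. = FALSE)
    if (any(coherence_links$weight < 0 | coherence_links$weight > 1))
      stop("mixing weights must lie in [0, 1]", call. = FALSE)
    ends <- c(paste(coherence_links$chan_a, coherence_links$band),
              paste(coherence_links$chan_b, coherence_links$band))
    if (anyDuplicated(ends))
      stop("a channel may appear in at most one coherence link per band",
           call. = FALSE)
  }
  if (!is.null(artifacts)) {
    need <- c("time_s", "amplitude_mv", "width_s")
    if (!all(need %in% names(artifacts)))
      stop("`artifacts` needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(artifacts$time_s < 0 | artifacts$time_s >= duration_s))
      stop("artifact times must lie within [0, duration_s)", call. = FALSE)
  }
  structure(
    list(fs_hz = fs_hz, duration_s = duration_s,
         band_amplitudes = band_amplitudes,
         coherence_links = coherence_links,
         pink_noise_rms = pink_noise_rms,
         artifacts = artifacts, seed = as.integer(seed)),
    class = "lfp_sim_spec"
  )
}

#' Add rectangular artifact pulses to a signal
#'
#' @param signal Channels x samples numeric matrix (mV).
#' @param fs_hz Sampling rate in Hz.
#' @param artifacts Data frame with columns `time_s`, `amplitude_mv`,
#'   `width_s`, and optionally `channel` (row index, default 1).
#' @return The signal with pulses added.
#' @export
inject_artifacts <- function(signal, fs_hz, artifacts) {
  if (is.null(artifacts) || nrow(artifacts) == 0L) return(signal)
  n <- ncol(signal)
  for (i in seq_len(nrow(artifacts))) {
    t0 <- artifacts$time_s[i]
    w <- artifacts$width_s[i]
    ch <- if ("channel" %in% names(artifacts)) artifacts$channel[i] else 1L
    i0 <- floor(t0 * fs_hz) + 1L
    i1 <- min(n, floor((t0 + w) * fs_hz))
    if (i0 < 1L || i0 > n)
      stop(sprintf("artifact at t = %g s lies outside the record", t0),
           call. = FALSE)
    signal[ch, i0:i1] <- signal[ch, i0:i1] + artifacts$amplitude_mv[i]
  }
  signal
}

#' Simulate one recording session
#'
#' Each channel is the sum of six independent band-limited components (one per
#' canonical band, at the specified RMS amplitudes), shared latent sources on
#' coherence-linked pairs, a 1/f background, and any injected artifacts.
#'
#' @param spec An [simulation_spec()] object.
#' @param rat_id,sex,estrous_phase,session_type,intake_g_per_kg Session
#'   metadata, copied through to the returned [lfp_session()].
#' @return An `lfp_session`.
#' @examples
#' s <- simulate_session(simulation_spec(duration_s = 6, seed = 7), "r1", "male")
#' dim(s$signal)
#' @export
simulate_session <- function(spec, rat_id = "sim", sex = "male",
                             estrous_phase = "not_applicable",
                             session_type = "baseline",
                             intake_g_per_kg = NA_real_) {
  stopifnot(inherits(spec, "lfp_sim_spec"))
  chans <- lfp_channels()
  bands <- lfp_bands()
  n <- round(spec$duration_s * spec$fs_hz)
  sig <- with_seed(spec$seed, {
    out <- matrix(0, nrow = length(chans), ncol = n,
                  dimnames = list(chans, NULL))
    for (b in seq_len(nrow(bands))) {
      band <- c(bands$low_hz[b], bands$high_hz[b])
      links <- spec$coherence_links
      links <- if (is.null(links)) NULL else
        links[links$band == bands$name[b], , drop = FALSE]
      # weights of channels tied to a shared latent source in this band
      w <- stats::setNames(numeric(length(chans)), chans)
      shared <- list()
      if (!is.null(links) && nrow(links) > 0L) {
        for (l in seq_len(nrow(links))) {
          s <- band_limited_noise(band, spec$duration_s, spec$fs_hz, 1)
          shared[[links$chan_a[l]]] <- s
          shared[[links$chan_b[l]]] <- s
          w[links$chan_a[l]] <- links$weight[l]
          w[links$chan_b[l]] <- links$weight[l]
        }
      }
      for (ci in seq_along(chans)) {
        amp <- spec$band_amplitudes[ci, b]
        if (amp == 0) next
        ch <- chans[ci]
        private <- band_limited_noise(band, spec$duration_s, spec$fs_hz, 1)
        comp <- if (!is.null(shared[[ch]]))
          w[ch] * shared[[ch]] + sqrt(1 - w[ch]^2) * private
        else private
        out[ci, ] <- out[ci, ] + amp * comp
      }
    }
    if (spec$pink_noise_rms > 0) {
      for (ci in seq_along(chans))
        out[ci, ] <- out[ci, ] +
          pink_noise(spec$duration_s, spec$fs_hz, spec$pink_noise_rms)
    }
    inject_artifacts(out, spec$fs_hz, spec$artifacts)
  })
  lfp_session(sig, spec$fs_hz, rat_id, sex, estrous_phase, session_type,
              intake_g_per_kg)
}

#' Specify a simulated cohort
#'
#' Defines a two-group cohort (labelled male/female) with per-rat random
#' effects and an optional group effect on chosen generating amplitudes.
#' Effect sizes are expressed on the log-amplitude scale in units of the
#' generating within-group standard deviation
#' `sqrt(rat_random_effect_sd^2 + session_jitter_sd^2)`, so an effect of d
#' shifts the target channel/band log-power by d of its own generating SDs.
#'
#' @param n_rats_per_group Number of rats in each of the two groups (>= 2).
#' @param recordings_per_rat Sessions recorded per rat (>= 1).
#' @param group_effect Data frame with columns `channel`, `band`,
#'   `effect_size`; applied multiplicatively to group 2 (female) amplitudes.
#'   `NULL` for no effect.
#' @param effect_scale Scale on which `effect_size` is expressed.
#'   `"feature_sd"` (default): units of the extracted band-power feature's
#'   within-group SD, calibrated empirically from a small no-effect pilot
#'   cohort so the shift survives normalization and spectral-estimation
#'   noise end-to-end. `"generating_sd"`: units of the generating
#'   log-amplitude SD `sqrt(rat_random_effect_sd^2 + session_jitter_sd^2)`
#'   (cheaper, no pilot, but the realized feature-level shift is smaller).
#' @param rat_random_effect_sd SD of per-rat log-amplitude offsets (drawn once
#'   per rat, shared by all its sessions).
#' @param session_jitter_sd SD of per-session log-amplitude jitter.
#' @param base_spec Session-level [simulation_spec()] template.
#' @param seed Integer seed.
#' @return An object of class `lfp_cohort_spec`.
#' @export
cohort_spec <- function(n_rats_per_group = 10, recordings_per_rat = 2,
                        group_effect = NULL,
                        effect_scale = c("feature_sd", "generating_sd"),
                        rat_random_effect_sd = 0.1,
                        session_jitter_sd = 0.05,
                        base_spec = simulation_spec(),
                        seed = 1L) {
  effect_scale <- match.arg(effect_scale)
  stopifnot(n_rats_per_group >= 2, recordings_per_rat >= 1,
            rat_random_effect_sd >= 0, session_jitter_sd >= 0,
            inherits(base_spec, "lfp_sim_spec"))
  if (!is.null(group_effect)) {
    need <- c("channel", "band", "effect_size")
    if (!all(need %in% names(group_effect)))
      stop("`group_effect` needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (!all(group_effect$channel %in% lfp_channels()) ||
        !all(group_effect$band %in% lfp_bands()$name))
      stop("unknown channel or band in `group_effect`", call. = FALSE)
  }
  structure(
    list(n_rats_per_group = n_rats_per_group,
         recordings_per_rat = recordings_per_rat,
         group_effect = group_effect, effect_scale = effect_scale,
         rat_random_effect_sd = rat_random_effect_sd,
         session_jitter_sd = session_jitter_sd,
         base_spec = base_spec, seed = as.integer(seed)),
    class = "lfp_cohort_spec"
  )
}

# Empirical effect calibration: simulate a no-effect pilot cohort (8 rats x
# 3 sessions with the cohort's random effects), extract features, and measure
# each target feature's within-group coefficient of variation and mean power
# share. Two steps give the amplitude multiplier m whose end-to-end shift of
# the extracted feature equals d pooled within-group SDs:
# 1. The multiplicative shift e^Delta satisfying
#      (e^Delta - 1) = d * cv * sqrt((1 + e^(2*Delta)) / 2)
#    accounts for the shifted group's proportionally inflated SD (pooled-SD
#    effect-size convention).
# 2. Solving 2*log(m) - log(1 + s*(m^2 - 1)) = Delta accounts for the target
#    band inflating its own normalization denominator (power share s).
calibrate_group_effect <- function(cohort) {
  ge <- cohort$group_effect
  chans <- lfp_channels()
  bands <- lfp_bands()$name
  pilot <- cohort
  pilot$group_effect <- NULL
  pilot$n_rats_per_group <- 4L
  pilot$recordings_per_rat <- 3L
  pilot$seed <- as.integer(derive_seed(cohort$seed, 7919))
  fs <- cohort$base_spec$fs_hz
  pre <- preprocess_config(
    downsample_factor = if (fs / 5 / 2 > 90) 5L else 1L)
  ones <- matrix(1, length(chans), length(bands),
                 dimnames = list(chans, bands))
  fm0 <- extract_feature_matrix(simulate_cohort_impl(pilot, ones)$sessions,
                                pre)
  mult <- numeric(nrow(ge))
  delta_wanted <- numeric(nrow(ge))
  solve_m <- function(delta, share, d) {
    gap_m <- function(m) 2 * log(m) - log(1 + share * (m^2 - 1)) - delta
    stats::uniroot(gap_m, lower = if (d > 0) 1 else 1e-3,
                   upper = if (d > 0) 1e3 else 1, tol = 1e-8)$root
  }
  feat_names <- paste0("pow_", ge$channel, "_", ge$band)
  shares <- numeric(nrow(ge))
  for (i in seq_len(nrow(ge))) {
    v <- fm0[[feat_names[i]]]
    cv <- stats::sd(v) / mean(v)
    shares[i] <- mean(v) / 100
    d <- ge$effect_size[i]
    if (d == 0 || cv == 0) { mult[i] <- 1; next }
    gap_delta <- function(delta)
      (exp(delta) - 1) - d * cv * sqrt((1 + exp(2 * delta)) / 2)
    delta <- stats::uniroot(gap_delta,
                            lower = if (d > 0) 0 else -20,
                            upper = if (d > 0) 20 else 0,
                            tol = 1e-10)$root
    # a percent-normalized feature cannot exceed 100: the achievable log
    # shift is bounded by -log(share)
    cap <- 0.95 * (-log(shares[i]))
    if (delta > cap) {
      warning("requested effect of ", d, " within-group SDs on ",
              feat_names[i], " exceeds the normalization ceiling; capped",
              call. = FALSE)
      delta <- cap
    }
    delta_wanted[i] <- delta
    mult[i] <- solve_m(delta, shares[i], d)
  }
  if (all(mult == 1)) return(mult)
  # verification pass: apply the candidate multipliers to a second pilot and
  # correct for unmodeled dilution (e.g. the in-band 1/f noise floor, which
  # the multiplier does not scale)
  pilot2 <- pilot
  pilot2$seed <- as.integer(derive_seed(cohort$seed, 104729))
  gm <- ones
  for (i in seq_len(nrow(ge)))
    gm[ge$channel[i], ge$band[i]] <- mult[i]
  sim2 <- simulate_cohort_impl(pilot2, gm)
  fm2 <- extract_feature_matrix(sim2$sessions, pre)
  grp2 <- sim2$manifest$sex == "female"
  for (i in seq_len(nrow(ge))) {
    if (mult[i] == 1) next
    v <- fm2[[feat_names[i]]]
    delta_obs <- log(mean(v[grp2])) - log(mean(v[!grp2]))
    kappa <- delta_obs / delta_wanted[i]
    if (is.finite(kappa) && kappa > 0.2 && kappa < 5)
      mult[i] <- solve_m(delta_wanted[i] / kappa, shares[i],
                         ge$effect_size[i])
  }
  mult
}

#' Simulate a balanced two-group cohort
#'
#' Generates `n_rats_per_group` rats per group (group 1 male, group 2 female),
#' each with `recordings_per_rat` sessions. Per-rat amplitude offsets are
#' drawn once per rat; session jitter is drawn per session; the group effect
#' multiplies group 2's generating amplitudes at the targeted channel/band.
#' Female sessions cycle through the estrous phases.
#'
#' @param cohort An [cohort_spec()] object.
#' @return A list with `sessions` (list of `lfp_session`) and `manifest`
#'   (data frame: rat_id, sex, estrous_phase, session_type, intake_g_per_kg).
#' @export
simulate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "lfp_cohort_spec"))
  chans <- lfp_channels()
  bands <- lfp_bands()$name
  sigma <- sqrt(cohort$rat_random_effect_sd^2 + cohort$session_jitter_sd^2)
  group_mult <- matrix(1, length(chans), length(bands),
                       dimnames = list(chans, bands))
  if (!is.null(cohort$group_effect)) {
    ge <- cohort$group_effect
    if (cohort$effect_scale == "feature_sd") {
      mult <- calibrate_group_effect(cohort)
      for (i in seq_len(nrow(ge)))
        group_mult[ge$channel[i], ge$band[i]] <- mult[i]
    } else if (sigma > 0) {
      for (i in seq_len(nrow(ge)))
        group_mult[ge$channel[i], ge$band[i]] <-
          exp(ge$effect_size[i] * sigma)
    }
  }
  simulate_cohort_impl(cohort, group_mult)
}

# Generate the cohort's sessions given the (already calibrated) amplitude
# multiplier matrix applied to group 2.
simulate_cohort_impl <- function(cohort, group_mult) {
  chans <- lfp_channels()
  bands <- lfp_bands()$name
  base <- cohort$base_spec
  phases <- c("diestrus", "proestrus", "estrus")
  sessions <- list()
  rows <- list()
  with_seed(cohort$seed, {
    for (g in 1:2) {
      sex <- c("male", "female")[g]
      for (r in seq_len(cohort$n_rats_per_group)) {
        rat_id <- sprintf("%s%02d", c("M", "F")[g], r)
        rat_mult <- exp(matrix(
          stats::rnorm(length(chans) * length(bands), 0,
                       cohort$rat_random_effect_sd),
          length(chans), length(bands)))
        for (k in seq_len(cohort$recordings_per_rat)) {
          jit <- exp(matrix(
            stats::rnorm(length(chans) * length(bands), 0,
                         cohort$session_jitter_sd),
            length(chans), length(bands)))
          amps <- base$band_amplitudes * rat_mult * jit
          if (g == 2L) amps <- amps * group_mult
          sess_seed <- sample.int(.Machine$integer.max, 1L)
          spec <- simulation_spec(
            fs_hz = base$fs_hz, duration_s = base$duration_s,
            band_amplitudes = amps,
            coherence_links = base$coherence_links,
            pink_noise_rms = base$pink_noise_rms,
            artifacts = base$artifacts, seed = sess_seed)
          phase <- if (sex == "female") phases[(k - 1L) %% 3L + 1L] else
            "not_applicable"
          sessions[[length(sessions) + 1L]] <-
            simulate_session(spec, rat_id, sex, phase)
          rows[[length(rows) + 1L]] <- data.frame(
            rat_id = rat_id, sex = sex, estrous_phase = phase,
            session_type = "baseline", intake_g_per_kg = NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  list(sessions = sessions, manifest = do.call(rbind, rows))
}

#' Simulate continuous intake outcomes from features
#'
#' Generates per-session alcohol intake (g/kg) as a sparse linear function of
#' named features plus Gaussian noise, clipped at zero (intake cannot be
#' negative). Returns the ground-truth weights alongside for recovery checks.
#'
#' @param features A feature matrix: data frame or matrix containing the
#'   canonical feature columns (see [lfp_feature_names()]).
#' @param weights Named numeric vector; names must be canonical feature names
#'   present in `features`.
#' @param noise_sd SD of additive Gaussian noise (g/kg).
#' @param intercept Baseline intake (g/kg).
#' @param seed Optional integer seed.
#' @return A list with `intake` (numeric per row), `weights`, `intercept`.
#' @export
simulate_intake_outcomes <- function(features, weights, noise_sd = 0,
                                     intercept = 1, seed = NULL) {
  bad <- setdiff(names(weights), lfp_feature_names())
  if (length(bad))
    stop("unknown feature name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(names(weights) %in% colnames(features)))
    stop("`features` is missing weighted columns", call. = FALSE)
  x <- as.matrix(as.data.frame(features)[, names(weights), drop = FALSE])
  lin <- intercept + as.numeric(x %*% weights)
  eps <- with_seed(seed, stats::rnorm(nrow(x), 0, noise_sd))
  list(intake = pmax(0, lin + eps), weights = weights, intercept = intercept)
}
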