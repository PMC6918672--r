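# Welch power spectral densities, magnitude-squared coherence, and the
# canonical 60-feature vector (24 normalized band powers + 36 normalized
# band coherences).

#' Spectral configuration
#'
#' @param psd_window_s Welch window length for PSDs in seconds (default 1.6;
#'   at 400 Hz: 640 samples, 0.625 Hz bins).
#' @param psd_overlap Fractional overlap between PSD windows (default 0.5).
#' @param coh_window_s Window length for coherence in seconds (default 1.3;
#'   at 400 Hz: 520 samples, ~0.769 Hz bins).
#' @param coh_overlap Fractional overlap between coherence windows
#'   (default 0.5).
#' @param norm_low_hz,norm_high_hz Normalization range for both power and
#'   coherence (defaults 1 and 90 Hz, start of delta to end of high gamma).
#' @param notch_exclusion_hz Frequency range excluded from normalization to
#'   account for the 60-Hz notch (default c(59, 61), inclusive of both edges).
#' @return An object of class `lfp_spectral_config`.
#' @export
spectral_config <- function(psd_window_s = 1.6, psd_overlap = 0.5,
                            coh_window_s = 1.3, coh_overlap = 0.5,
                            norm_low_hz = 1, norm_high_hz = 90,
                            notch_exclusion_hz = c(59, 61)) {
  stopifnot(psd_window_s > 0, coh_window_s > 0,
            psd_overlap >= 0, psd_overlap < 1,
            coh_overlap >= 0, coh_overlap < 1,
            norm_low_hz < norm_high_hz,
            length(notch_exclusion_hz) == 2L,
            notch_exclusion_hz[1] <= notch_exclusion_hz[2])
  structure(
    list(psd_window_s = psd_window_s, psd_overlap = psd_overlap,
         coh_window_s = coh_window_s, coh_overlap = coh_overlap,
         norm_low_hz = norm_low_hz, norm_high_hz = norm_high_hz,
         notch_exclusion_hz = notch_exclusion_hz),
    class = "lfp_spectral_config"
  )
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Averaged one-sided auto-/cross-spectra over all fully contained Hamming
# windows. Returns freq, sxx, syy (NULL if y missing), sxy.
welch_spectra <- function(x, y = NULL, fs_hz, window_s, overlap) {
  win <- round(window_s * fs_hz)
  if (length(x) < win)
    stop(sprintf("signal of %d samples is shorter than the %d-sample window",
                 length(x), win), call. = FALSE)
  hop <- max(1L, round(win * (1 - overlap)))
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  w <- hamming_window(win)
  nbins <- win %/% 2L + 1L
  sxx <- numeric(nbins)
  syy <- if (!is.null(y)) numeric(nbins) else NULL
  sxy <- if (!is.null(y)) complex(nbins) else NULL
  for (s0 in starts) {
    seg <- s0:(s0 + win - 1L)
    fx <- stats::fft(x[seg] * w)[seq_len(nbins)]
    sxx <- sxx + Re(fx * Conj(fx))
    if (!is.null(y)) {
      fy <- stats::fft(y[seg] * w)[seq_len(nbins)]
      syy <- syy + Re(fy * Conj(fy))
      sxy <- sxy + Conj(fx) * fy
    }
  }
  scale <- 1 / (fs_hz * sum(w^2) * length(starts))
  one_sided <- rep(2, nbins)
  one_sided[1] <- 1
  if (win %% 2L == 0L) one_sided[nbins] <- 1
  list(freq = (seq_len(nbins) - 1L) * fs_hz / win,
       n_windows = length(starts),
       sxx = sxx * scale * one_sided,
       syy = if (!is.null(y)) syy * scale * one_sided else NULL,
       sxy = if (!is.null(y)) sxy * scale * one_sided else NULL)
}

#' Welch power spectral density of one epoch channel
#'
#' Average of Hamming-windowed periodograms over all fully contained windows
#' (windows that do not fit are discarded; no zero padding). For a 3-s epoch
#' at 400 Hz with the default 1.6-s window and 50% overlap this averages two
#' windows and yields 0.625-Hz bins.
#'
#' @param x Numeric vector: one channel of one epoch (mV).
#' @param fs_hz Sampling rate (Hz).
#' @param config An [spectral_config()].
#' @return List of class `lfp_spectrum` with `freq` (Hz), `values`
#'   (power density, mV^2/Hz) and `kind = "psd"`.
#' @export
welch_psd <- function(x, fs_hz, config = spectral_config()) {
  sp <- welch_spectra(x, NULL, fs_hz, config$psd_window_s, config$psd_overlap)
  structure(list(freq = sp$freq, values = sp$sxx, kind = "psd"),
            class = "lfp_spectrum")
}

#' Representative session PSD for one channel
#'
#' Arithmetic mean, in linear power units, of the per-epoch Welch PSDs.
#'
#' @param epochs An [lfp_epochs()] object.
#' @param channel Channel name (see [lfp_channels()]) or row index.
#' @param config An [spectral_config()].
#' @return An `lfp_spectrum` of kind `"psd"`.
#' @export
session_psd <- function(epochs, channel, config = spectral_config()) {
  stopifnot(inherits(epochs, "lfp_epochs"))
  if (length(epochs$epochs) == 0L)
    stop("empty epoch set: no data to average", call. = FALSE)
  ci <- if (is.character(channel)) match(channel, lfp_channels()) else channel
  if (is.na(ci)) stop("unknown channel: ", channel, call. = FALSE)
  acc <- NULL
  freq <- NULL
  for (e in epochs$epochs) {
    sp <- welch_psd(e[ci, ], epochs$fs_hz, config)
    if (is.null(acc)) { acc <- sp$values; freq <- sp$freq }
    else acc <- acc + sp$values
  }
  structure(list(freq = freq, values = acc / length(epochs$epochs),
                 kind = "psd"),
            class = "lfp_spectrum")
}

#' Magnitude-squared coherence of one epoch channel pair
#'
#' MSC(f) = |Sxy|^2 / (Sxx * Syy) from window-averaged cross- and
#' auto-spectra over the epoch's sliding Hamming windows. For a 3-s epoch at
#' 400 Hz with the default 1.3-s window and 50% overlap this averages three
#' windows. A configuration leaving only one window is rejected: with a
#' single window MSC is identically 1 and carries no information.
#'
#' @param x,y Numeric vectors of equal length: the two channels of one epoch.
#' @param fs_hz Sampling rate (Hz).
#' @param config An [spectral_config()].
#' @return An `lfp_spectrum` with values in \[0, 1\] and `kind = "coherence"`.
#' @export
msq_coherence <- function(x, y, fs_hz, config = spectral_config()) {
  if (length(x) != length(y))
    stop("channels must have the same length", call. = FALSE)
  sp <- welch_spectra(x, y, fs_hz, config$coh_window_s, config$coh_overlap)
  if (sp$n_windows < 2L)
    stop("coherence needs at least 2 windows per epoch; got ",
         sp$n_windows, call. = FALSE)
  denom <- sp$sxx * sp$syy
  msc <- ifelse(denom > 0, Re(sp$sxy * Conj(sp$sxy)) / denom, 0)
  msc <- pmin(pmax(msc, 0), 1)
  structure(list(freq = sp$freq, values = msc, kind = "coherence"),
            class = "lfp_spectrum")
}

#' Session coherence spectrum for one channel pair
#'
#' Cross- and auto-spectra are averaged over the sliding windows of every
#' epoch (windows never straddle epoch boundaries, so the excision joins
#' between non-contiguous epochs contribute no phase discontinuities), and
#' the magnitude-squared coherence is formed once from the pooled averages.
#' Pooling at the spectra level is what keeps the estimator unbiased: the
#' per-epoch MSC of [msq_coherence()] carries the well-known upward
#' small-sample bias of order 1/(number of windows), which no amount of
#' averaging across epochs removes.
#'
#' @param epochs An [lfp_epochs()] object.
#' @param chan_a,chan_b Channel names or row indices.
#' @param config An [spectral_config()].
#' @return An `lfp_spectrum` of kind `"coherence"`.
#' @export
session_coherence <- function(epochs, chan_a, chan_b,
                              config = spectral_config()) {
  stopifnot(inherits(epochs, "lfp_epochs"))
  if (length(epochs$epochs) == 0L)
    stop("empty epoch set: no data to average", call. = FALSE)
  ia <- if (is.character(chan_a)) match(chan_a, lfp_channels()) else chan_a
  ib <- if (is.character(chan_b)) match(chan_b, lfp_channels()) else chan_b
  if (is.na(ia) || is.na(ib)) stop("unknown channel", call. = FALSE)
  sxx <- syy <- 0
  sxy <- 0 + 0i
  freq <- NULL
  n_win <- 0L
  for (e in epochs$epochs) {
    sp <- welch_spectra(e[ia, ], e[ib, ], epochs$fs_hz,
                        config$coh_window_s, config$coh_overlap)
    if (is.null(freq)) {
      freq <- sp$freq
      n_win <- sp$n_windows
    }
    sxx <- sxx + sp$sxx
    syy <- syy + sp$syy
    sxy <- sxy + sp$sxy
  }
  if (n_win * length(epochs$epochs) < 2L)
    stop("coherence needs at least 2 windows in total", call. = FALSE)
  denom <- sxx * syy
  msc <- ifelse(denom > 0, Re(sxy * Conj(sxy)) / denom, 0)
  structure(list(freq = freq, values = pmin(pmax(msc, 0), 1),
                 kind = "coherence"),
            class = "lfp_spectrum")
}

norm_mask <- function(freq, config) {
  in_range <- freq >= config$norm_low_hz & freq <= config$norm_high_hz
  excl <- freq >= config$notch_exclusion_hz[1] &
    freq <= config$notch_exclusion_hz[2]
  in_range & !excl
}

band_mask <- function(freq, low, high) freq >= low & freq <= high

#' Normalized band power features
#'
#' For each channel, power in each canonical band (PSD summed over the band's
#' bins, inclusive bounds) expressed as a percent of the total power from 1
#' to 90 Hz, excluding 59-61 Hz to account for the notch. All 24 features lie
#' in \[0, 100\] and are invariant to rescaling the signal.
#'
#' @param session_psds Named list of `lfp_spectrum` objects, one per channel,
#'   names matching [lfp_channels()].
#' @param config An [spectral_config()].
#' @return Named numeric vector of 24 features, `pow_<channel>_<band>`,
#'   channel-major.
#' @export
band_power_features <- function(session_psds, config = spectral_config()) {
  bands <- lfp_bands()
  out <- numeric(0)
  for (ch in lfp_channels()) {
    sp <- session_psds[[ch]]
    if (is.null(sp)) stop("missing PSD for channel ", ch, call. = FALSE)
    total <- sum(sp$values[norm_mask(sp$freq, config)])
    if (total <= 0)
      stop("zero total power on channel ", ch, " (degenerate signal)",
           call. = FALSE)
    v <- vapply(seq_len(nrow(bands)), function(b) {
      100 * sum(sp$values[band_mask(sp$freq, bands$low_hz[b],
                                    bands$high_hz[b])]) / total
    }, numeric(1))
    names(v) <- paste0("pow_", ch, "_", bands$name)
    out <- c(out, v)
  }
  out
}

#' Normalized band coherence features
#'
#' For each channel pair, the mean coherence within each canonical band
#' divided by that pair's broadband mean coherence (1-90 Hz, excluding
#' 59-61 Hz). Values are nonnegative; 1 means the band is as coherent as the
#' pair's broadband average.
#'
#' @param session_coherences Named list of `lfp_spectrum` objects, one per
#'   pair, names `"<chanA>-<chanB>"` following [lfp_channel_pairs()].
#' @param config An [spectral_config()].
#' @return Named numeric vector of 36 features, `coh_<chanA>-<chanB>_<band>`,
#'   pair-major.
#' @export
band_coherence_features <- function(session_coherences,
                                    config = spectral_config()) {
  bands <- lfp_bands()
  pairs <- lfp_channel_pairs()
  out <- numeric(0)
  for (i in seq_len(nrow(pairs))) {
    key <- paste0(pairs[i, 1], "-", pairs[i, 2])
    sp <- session_coherences[[key]]
    if (is.null(sp)) stop("missing coherence for pair ", key, call. = FALSE)
    broadband <- mean(sp$values[norm_mask(sp$freq, config)])
    if (broadband <= 0)
      stop("zero broadband coherence for pair ", key, call. = FALSE)
    v <- vapply(seq_len(nrow(bands)), function(b) {
      mean(sp$values[band_mask(sp$freq, bands$low_hz[b],
                               bands$high_hz[b])]) / broadband
    }, numeric(1))
    names(v) <- paste0("coh_", key, "_", bands$name)
    out <- c(out, v)
  }
  out
}

#' Extract the canonical 60-feature vector from an epoch set
#'
#' Computes the representative session PSD per channel and coherence spectrum
#' per channel pair, then assembles 24 normalized band power features followed
#' by 36 normalized band coherence features, in the fixed canonical order of
#' [lfp_feature_names()].
#'
#' @param epochs A non-empty [lfp_epochs()] object.
#' @param config An [spectral_config()].
#' @return Named numeric vector of length 60.
#' @export
extract_features <- function(epochs, config = spectral_config()) {
  stopifnot(inherits(epochs, "lfp_epochs"))
  if (length(epochs$epochs) == 0L)
    stop("cannot extract features from an empty epoch set", call. = FALSE)
  psds <- lapply(stats::setNames(lfp_channels(), lfp_channels()),
                 function(ch) session_psd(epochs, ch, config))
  pairs <- lfp_channel_pairs()
  cohs <- list()
  for (i in seq_len(nrow(pairs))) {
    key <- paste0(pairs[i, 1], "-", pairs[i, 2])
    cohs[[key]] <- session_coherence(epochs, pairs[i, 1], pairs[i, 2], config)
  }
  v <- c(band_power_features(psds, config),
         band_coherence_features(cohs, config))
  stopifnot(identical(names(v), lfp_feature_names()))
  v
}

#' Build a feature matrix from a list of sessions
#'
#' Preprocesses each session ([preprocess_session()]) and extracts its
#' 60-feature vector, returning one row per session with the session metadata
#' in the leading columns. This data frame (or its CSV serialization) is the
#' contract between the signal-processing half and the statistics half of
#' the pipeline.
#'
#' @param sessions List of [lfp_session()] objects.
#' @param pre_config An [preprocess_config()].
#' @param spec_config An [spectral_config()].
#' @return Data frame with columns `rat_id`, `sex`, `estrous_phase`,
#'   `session_type`, `intake_g_per_kg`, then the 60 canonical features.
#' @export
extract_feature_matrix <- function(sessions,
                                   pre_config = preprocess_config(),
                                   spec_config = spectral_config()) {
  rows <- lapply(sessions, function(s) {
    ep <- preprocess_session(s, pre_config)
    v <- extract_features(ep, spec_config)
    cbind(
      data.frame(rat_id = s$rat_id, sex = s$sex,
                 estrous_phase = s$estrous_phase,
                 session_type = s$session_type,
                 intake_g_per_kg = s$intake_g_per_kg,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(v), check.names = FALSE)
    )
  })
  do.call(rbind, rows)
}

#' Select the 60 canonical feature columns as a matrix
#'
#' @param features A feature matrix data frame (see
#'   [extract_feature_matrix()]).
#' @return Numeric matrix with the 60 canonical feature columns.
#' @export
feature_columns <- function(features) {
  miss <- setdiff(lfp_feature_names(), colnames(features))
  if (length(miss))
    stop("feature matrix is missing columns: ",
         paste(utils::head(miss, 3), collapse = ", "),
         if (length(miss) > 3) ", ..." else "", call. = FALSE)
  m <- as.matrix(as.data.frame(features)[, lfp_feature_names(), drop = FALSE])
  if (anyNA(m)) stop("feature matrix contains missing values", call. = FALSE)
  m
}
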