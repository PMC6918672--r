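# Raw session -> artifact-free, channel-aligned 3-s epochs.
# Stage order: 60-Hz notch -> decimate to 400 Hz -> amplitude-threshold
# artifact exclusion -> segmentation into 3-s epochs.

#' Preprocessing configuration
#'
#' @param notch_center_hz Line-noise frequency (default 60 Hz).
#' @param notch_order Overall order of the Chebyshev type I band-stop
#'   (default 4).
#' @param notch_bandwidth_hz Stop-band width centered on `notch_center_hz`
#'   (default 2, i.e. 59-61 Hz).
#' @param notch_ripple_db Passband ripple of the Chebyshev design in dB
#'   (default 0.25; the filter is applied forward-backward, doubling ripple
#'   and attenuation in dB).
#' @param downsample_factor Integer decimation factor (default 5:
#'   2 kHz -> 400 Hz).
#' @param artifact_threshold_mv Absolute amplitude threshold identifying
#'   artifacts (default 2 mV).
#' @param pre_window_s Seconds excluded before each artifact (default 0.0125,
#'   i.e. 12.5 ms).
#' @param post_window_s Seconds excluded after each artifact (default 40).
#' @param min_epoch_s Minimum length of a clean interval to be used
#'   (default 3).
#' @param segment_s Epoch length (default 3).
#' @return An object of class `lfp_preprocess_config`.
#' @export
preprocess_config <- function(notch_center_hz = 60, notch_order = 4,
                              notch_bandwidth_hz = 2, notch_ripple_db = 0.25,
                              downsample_factor = 5,
                              artifact_threshold_mv = 2.0,
                              pre_window_s = 0.0125, post_window_s = 40,
                              min_epoch_s = 3, segment_s = 3) {
  stopifnot(notch_center_hz > 0, notch_bandwidth_hz > 0, notch_order >= 2,
            notch_order %% 2 == 0, notch_ripple_db > 0,
            downsample_factor >= 1, downsample_factor == round(downsample_factor),
            artifact_threshold_mv > 0, pre_window_s >= 0, post_window_s >= 0,
            min_epoch_s > 0, segment_s > 0)
  structure(
    list(notch_center_hz = notch_center_hz, notch_order = notch_order,
         notch_bandwidth_hz = notch_bandwidth_hz,
         notch_ripple_db = notch_ripple_db,
         downsample_factor = as.integer(downsample_factor),
         artifact_threshold_mv = artifact_threshold_mv,
         pre_window_s = pre_window_s, post_window_s = post_window_s,
         min_epoch_s = min_epoch_s, segment_s = segment_s),
    class = "lfp_preprocess_config"
  )
}

as_signal_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Notch filter for line noise
#'
#' Chebyshev type I band-stop (order `notch_order` overall) covering
#' `notch_center_hz +/- notch_bandwidth_hz / 2`, applied forward-backward
#' (zero phase) to every channel so channels stay time-aligned.
#'
#' @param x Numeric vector or channels x samples matrix (mV).
#' @param fs_hz Sampling rate in Hz; must exceed `2 * notch_center_hz`.
#' @param config An [preprocess_config()].
#' @return Filtered signal with the same shape as the input.
#' @export
notch_filter <- function(x, fs_hz, config = preprocess_config()) {
  if (fs_hz <= 2 * config$notch_center_hz)
    stop(sprintf("fs = %g Hz violates Nyquist for a %g Hz notch",
                 fs_hz, config$notch_center_hz), call. = FALSE)
  edges <- config$notch_center_hz +
    c(-1, 1) * config$notch_bandwidth_hz / 2
  flt <- signal::cheby1(config$notch_order / 2, config$notch_ripple_db,
                        edges / (fs_hz / 2), type = "stop")
  vec <- !is.matrix(x)
  m <- as_signal_matrix(x)
  for (i in seq_len(nrow(m)))
    m[i, ] <- signal::filtfilt(flt, m[i, ])
  if (vec) drop(m) else m
}

#' Decimate a signal
#'
#' Anti-alias low-pass (64-tap FIR at the post-decimation Nyquist, applied
#' forward-backward for zero phase), then retention of every `factor`-th
#' sample. The analysis range extends to 90 Hz, so the post-decimation
#' Nyquist must stay above 90 Hz.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param fs_hz Input sampling rate (Hz).
#' @param factor Integer decimation factor.
#' @return List with `signal` (same orientation as input) and `fs_hz`
#'   (the new rate, `fs_hz / factor`).
#' @export
decimate_signal <- function(x, fs_hz, factor = 5) {
  stopifnot(factor >= 1, factor == round(factor))
  new_fs <- fs_hz / factor
  if (new_fs / 2 <= 90)
    stop(sprintf(
      "decimating %g Hz by %d gives Nyquist %g Hz <= 90 Hz; the 70-90 Hz band would alias",
      fs_hz, factor, new_fs / 2), call. = FALSE)
  if (factor == 1L) return(list(signal = x, fs_hz = fs_hz))
  b <- as.numeric(signal::fir1(64, 1 / factor))
  vec <- !is.matrix(x)
  m <- as_signal_matrix(x)
  keep <- seq(1L, ncol(m), by = factor)
  out <- matrix(0, nrow(m), length(keep))
  rownames(out) <- rownames(m)
  for (i in seq_len(nrow(m)))
    out[i, ] <- signal::filtfilt(b, 1, m[i, ])[keep]
  list(signal = if (vec) drop(out) else out, fs_hz = new_fs)
}

#' Artifact keep-mask
#'
#' Any sample exceeding `artifact_threshold_mv` in absolute value on any
#' channel marks an artifact. Each contiguous supra-threshold run excludes
#' the interval from `pre_window_s` before its first sample to `post_window_s`
#' after its last sample; overlapping exclusions merge. The returned mask is
#' the complement (TRUE = keep) and applies identically to all channels, so
#' retained data stay channel-aligned.
#'
#' @param x Channels x samples numeric matrix (mV).
#' @param fs_hz Sampling rate (Hz).
#' @param config An [preprocess_config()].
#' @return Logical vector over samples; TRUE where data are artifact-free.
#' @export
artifact_mask <- function(x, fs_hz, config = preprocess_config()) {
  m <- as_signal_matrix(x)
  n <- ncol(m)
  supra <- matrixStats_colAnys(abs(m) > config$artifact_threshold_mv)
  keep <- rep(TRUE, n)
  if (!any(supra)) return(keep)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tol <- 1e-9
  for (j in which(r$values)) {
    t_first <- (starts[j] - 1L) / fs_hz
    t_last <- (ends[j] - 1L) / fs_hz
    lo <- t_first - config$pre_window_s
    hi <- t_last + config$post_window_s
    i0 <- max(1L, ceiling(lo * fs_hz - tol) + 1L)
    i1 <- min(n, floor(hi * fs_hz + tol) + 1L)
    keep[i0:i1] <- FALSE
  }
  keep
}

# column-wise any() without extra deps
matrixStats_colAnys <- function(m) {
  if (nrow(m) == 1L) as.vector(m) else colSums(m) > 0L
}

#' Segment clean intervals into fixed epochs
#'
#' Every maximal artifact-free run at least `min_epoch_s` long is cut into
#' consecutive non-overlapping `segment_s`-second epochs from its start; the
#' remainder is discarded so epochs all cover the same amount of time.
#'
#' @param keep_mask Logical keep-mask over samples (from [artifact_mask()]).
#' @param fs_hz Sampling rate (Hz) of `x`.
#' @param x Channels x samples matrix, aligned with `keep_mask`.
#' @param config An [preprocess_config()].
#' @param session_ref Identifier carried into the resulting epoch set.
#' @return An [lfp_epochs()] object (possibly empty, with a warning).
#' @export
epoch_segments <- function(keep_mask, fs_hz, x,
                           config = preprocess_config(), session_ref = "") {
  m <- as_signal_matrix(x)
  if (length(keep_mask) != ncol(m))
    stop("`keep_mask` and signal are not aligned", call. = FALSE)
  seg_n <- round(config$segment_s * fs_hz)
  min_n <- round(config$min_epoch_s * fs_hz)
  epochs <- list()
  r <- rle(keep_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    len <- r$lengths[j]
    if (len < min_n) next
    n_seg <- len %/% seg_n
    for (k in seq_len(n_seg)) {
      i0 <- starts[j] + (k - 1L) * seg_n
      epochs[[length(epochs) + 1L]] <- m[, i0:(i0 + seg_n - 1L), drop = FALSE]
    }
  }
  if (length(epochs) == 0L)
    warning("no artifact-free epochs survived segmentation", call. = FALSE)
  lfp_epochs(epochs, fs_hz, session_ref, config$segment_s)
}

#' Preprocess a session end-to-end
#'
#' Applies, in order: 60-Hz notch at the native rate, decimation (2 kHz ->
#' 400 Hz by default), amplitude-threshold artifact exclusion on the
#' decimated signal, and segmentation into 3-s epochs.
#'
#' @param session An [lfp_session()].
#' @param config An [preprocess_config()].
#' @return An [lfp_epochs()] at the decimated rate.
#' @export
preprocess_session <- function(session, config = preprocess_config()) {
  stopifnot(inherits(session, "lfp_session"))
  filtered <- notch_filter(session$signal, session$fs_hz, config)
  dec <- decimate_signal(filtered, session$fs_hz, config$downsample_factor)
  keep <- artifact_mask(dec$signal, dec$fs_hz, config)
  epoch_segments(keep, dec$fs_hz, dec$signal, config, session$rat_id)
}
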