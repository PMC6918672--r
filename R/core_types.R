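#' Canonical frequency bands
#'
#' The six frequency bands used throughout the package, following established
#' rodent electrophysiology conventions: delta (1-4 Hz), theta (5-10 Hz),
#' alpha (11-14 Hz), beta (15-30 Hz), low gamma (45-65 Hz) and high gamma
#' (70-90 Hz). Bands are non-overlapping and ordered by increasing frequency;
#' band membership of a spectral bin is inclusive at both edges.
#'
#' @return A data frame with columns `name`, `low_hz`, `high_hz`, one row per
#'   band in canonical order.
#' @examples
#' lfp_bands()
#' @export
lfp_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
    low_hz = c(1, 5, 11, 15, 45, 70),
    high_hz = c(4, 10, 14, 30, 65, 90),
    stringsAsFactors = FALSE
  )
}

#' Canonical recording channels
#'
#' The fixed four-channel montage: left and right medial prefrontal cortex
#' (mPFC, at the prelimbic/infralimbic junction) and left and right nucleus
#' accumbens shell (NAcSh). Order is canonical and used everywhere features
#' are enumerated.
#'
#' @return Character vector of the 4 channel names.
#' @export
lfp_channels <- function() {
  c("L_mPFC", "R_mPFC", "L_NAcSh", "R_NAcSh")
}

#' Canonical channel pairs
#'
#' The 6 unordered channel pairs, enumerated in lexicographic order of
#' (first, second) under the canonical channel order of [lfp_channels()].
#'
#' @return A two-column character matrix with 6 rows.
#' @export
lfp_channel_pairs <- function() {
  ch <- lfp_channels()
  idx <- utils::combn(length(ch), 2)
  cbind(first = ch[idx[1, ]], second = ch[idx[2, ]])
}

#' Canonical feature names
#'
#' Enumerates the 60 feature names in their fixed canonical order: 24 power
#' features `pow_<channel>_<band>` (channel-major, bands innermost), then 36
#' coherence features `coh_<chanA>-<chanB>_<band>` (pair-major, bands
#' innermost). This order is identical across all sessions and runs.
#'
#' @return Character vector of length 60.
#' @examples
#' head(lfp_feature_names())
#' @export
lfp_feature_names <- function() {
  bands <- lfp_bands()$name
  pow <- as.vector(vapply(
    lfp_channels(),
    function(ch) paste0("pow_", ch, "_", bands),
    character(length(bands))
  ))
  pairs <- lfp_channel_pairs()
  coh <- as.vector(vapply(
    seq_len(nrow(pairs)),
    function(i) paste0("coh_", pairs[i, 1], "-", pairs[i, 2], "_", bands),
    character(length(bands))
  ))
  c(pow, coh)
}

valid_sexes <- c("male", "female")
valid_phases <- c("diestrus", "proestrus", "estrus", "not_applicable")
valid_session_types <- c("baseline", "alcohol")

#' Construct a recording session
#'
#' Bundles a raw multichannel signal with its metadata and validates the
#' contract assumed by the rest of the pipeline: exactly 4 channels (rows),
#' signal in millivolts, males carry `estrous_phase = "not_applicable"`, and
#' alcohol intake is present exactly for alcohol sessions.
#'
#' @param signal Numeric matrix, channels x samples, in millivolts. Rows must
#'   follow the canonical channel order of [lfp_channels()].
#' @param fs_hz Sampling rate in Hz.
#' @param rat_id Identifier of the animal.
#' @param sex `"male"` or `"female"`.
#' @param estrous_phase One of `"diestrus"`, `"proestrus"`, `"estrus"`,
#'   `"not_applicable"`.
#' @param session_type `"baseline"` or `"alcohol"`.
#' @param intake_g_per_kg Alcohol consumed in g per kg body weight; required
#'   for alcohol sessions, must be `NA` for baseline sessions.
#' @return An object of class `lfp_session`.
#' @export
lfp_session <- function(signal, fs_hz, rat_id, sex,
                        estrous_phase = "not_applicable",
                        session_type = "baseline",
                        intake_g_per_kg = NA_real_) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric channels x samples matrix", call. = FALSE)
  if (nrow(signal) != length(lfp_channels()))
    stop("`signal` must have exactly ", length(lfp_channels()),
         " rows (channels), got ", nrow(signal), call. = FALSE)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("`fs_hz` must be a positive scalar", call. = FALSE)
  sex <- match.arg(sex, valid_sexes)
  estrous_phase <- match.arg(estrous_phase, valid_phases)
  session_type <- match.arg(session_type, valid_session_types)
  if (sex == "male" && estrous_phase != "not_applicable")
    stop("males must have estrous_phase = \"not_applicable\"", call. = FALSE)
  if (session_type == "alcohol" && is.na(intake_g_per_kg))
    stop("alcohol sessions require `intake_g_per_kg`", call. = FALSE)
  if (session_type == "baseline" && !is.na(intake_g_per_kg))
    stop("baseline sessions must not carry `intake_g_per_kg`", call. = FALSE)
  if (!is.na(intake_g_per_kg) && intake_g_per_kg < 0)
    stop("`intake_g_per_kg` must be nonnegative", call. = FALSE)
  structure(
    list(
      signal = signal,
      fs_hz = fs_hz,
      duration_s = ncol(signal) / fs_hz,
      rat_id = as.character(rat_id),
      sex = sex,
      estrous_phase = estrous_phase,
      session_type = session_type,
      intake_g_per_kg = intake_g_per_kg
    ),
    class = "lfp_session"
  )
}

#' @export
print.lfp_session <- function(x, ...) {
  cat(sprintf(
    "<lfp_session> rat %s (%s, %s, %s): %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$rat_id, x$sex, x$estrous_phase, x$session_type,
    nrow(x$signal), ncol(x$signal), x$fs_hz, x$duration_s
  ))
  invisible(x)
}

#' Construct an epoch set
#'
#' An epoch set holds the artifact-free, channel-aligned 3-s segments of one
#' preprocessed session. All epochs share the shape
#' `4 x round(fs_hz * epoch_len_s)` and cover identical time intervals on all
#' channels (required for coherence).
#'
#' @param epochs List of channels x samples numeric matrices.
#' @param fs_hz Sampling rate (Hz) of the epochs (post-decimation).
#' @param session_ref Identifier of the originating session.
#' @param epoch_len_s Epoch length in seconds (default 3).
#' @return An object of class `lfp_epochs`.
#' @export
lfp_epochs <- function(epochs, fs_hz, session_ref = "", epoch_len_s = 3) {
  n_samp <- round(fs_hz * epoch_len_s)
  for (e in epochs) {
    if (!is.matrix(e) || nrow(e) != length(lfp_channels()) || ncol(e) != n_samp)
      stop("every epoch must be a ", length(lfp_channels()), " x ", n_samp,
           " matrix", call. = FALSE)
  }
  structure(
    list(epochs = epochs, fs_hz = fs_hz, session_ref = as.character(session_ref),
         epoch_len_s = epoch_len_s),
    class = "lfp_epochs"
  )
}

#' @export
print.lfp_epochs <- function(x, ...) {
  cat(sprintf("<lfp_epochs> session %s: %d epochs of %.1f s @ %g Hz\n",
              x$session_ref, length(x$epochs), x$epoch_len_s, x$fs_hz))
  invisible(x)
}

#' @export
length.lfp_epochs <- function(x) length(x$epochs)
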