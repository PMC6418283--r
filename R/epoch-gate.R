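#' Extract a stimulus-locked epoch from a continuous recording
#'
#' Returns the segment of `duration_s` seconds beginning at the stimulus
#' onset. Sample indexing is 0-based and half-open: the epoch covers
#' samples `[onset_sample, onset_sample + duration_s * fs)`, with the onset
#' sample included.
#'
#' @param recording An [eeg_recording()].
#' @param onset_sample 0-based sample offset of the stimulus onset.
#' @param duration_s Epoch duration, seconds.
#' @return An [eeg_recording()] of `duration_s * fs` samples.
#' @export
extract_epoch <- function(recording, onset_sample, duration_s = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  n <- duration_s * recording$fs
  if (abs(n - round(n)) > 1e-9) stop("duration_s * fs must be an integer")
  n <- as.integer(round(n))
  total <- ncol(recording$data)
  if (onset_sample < 0 || onset_sample + n > total) {
    stop(sprintf(
      "epoch [%d, %d) out of range for a recording of %d samples",
      onset_sample, onset_sample + n, total))
  }
  eeg_recording(recording$data[, (onset_sample + 1):(onset_sample + n),
                               drop = FALSE],
                recording$fs, recording$labels)
}

#' Gate a trial by the fixation ring
#'
#' A trial is valid if and only if every gaze sample lies within the
#' fixation ring: eccentricity less than or equal to `ring_radius`
#' (the boundary is inclusive — only gaze strictly beyond the ring
#' invalidates a trial).
#'
#' @param gaze Matrix or data frame with columns `x_deg`, `y_deg`
#'   (degrees from fixation).
#' @param ring_radius Ring radius, degrees.
#' @return Logical scalar.
#' @export
gate_trial <- function(gaze, ring_radius = 1.5) {
  gaze <- as.matrix(gaze)
  if (nrow(gaze) == 0) stop("empty gaze trace")
  ecc <- sqrt(gaze[, 1]^2 + gaze[, 2]^2)
  all(ecc <= ring_radius)
}

#' Re-apply gaze gating to a session
#'
#' Recomputes every trial's validity flag from its stored gaze trace; used
#' when sessions come from disk rather than the simulator.
#'
#' @param session An `ssvep_session`.
#' @param ring_radius Ring radius, degrees.
#' @return The session with updated `valid` flags.
#' @export
gate_session <- function(session, ring_radius = 1.5) {
  stopifnot(inherits(session, "ssvep_session"))
  session$trials <- lapply(session$trials, function(tr) {
    tr$valid <- gate_trial(tr$gaze, ring_radius)
    tr
  })
  session
}

#' Filter every valid trial epoch of a session
#'
#' Applies the preprocessing chain of [apply_filters()] to the EEG of each
#' valid trial (invalid trials are never analyzed and are left untouched).
#'
#' @param session An `ssvep_session`.
#' @param spec A [filter_spec()].
#' @return The session with filtered valid-trial epochs.
#' @export
preprocess_session <- function(session, spec = filter_spec()) {
  stopifnot(inherits(session, "ssvep_session"))
  chain <- .filter_chain(spec, session$fs_eeg)
  padlen <- as.integer(round(0.5 * session$fs_eeg))
  session$trials <- lapply(session$trials, function(tr) {
    if (tr$valid) {
      filt <- t(filtfilt_sos(t(tr$eeg), chain, padlen))
      dimnames(filt) <- dimnames(tr$eeg)
      tr$eeg <- filt
    }
    tr
  })
  session
}
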