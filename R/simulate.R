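#' Evoked amplitude at a visual-field position
#'
#' Deterministic forward model of SSVEP amplitude as a function of stimulus
#' position: a Gaussian falloff with eccentricity, times a lower-visual-field
#' boost,
#' \deqn{A(x, y) = A_0 \exp(-e^2 / 2\sigma_r^2)\,(1 + \beta\,[y < 0]),}
#' with \eqn{e = \sqrt{x^2 + y^2}} the eccentricity in degrees.
#'
#' @param params A [sim_params()] object.
#' @param position Numeric length-2 vector `(x, y)` in degrees.
#' @return Evoked amplitude in signal units.
#' @export
simulate_amplitude <- function(params, position) {
  stopifnot(inherits(params, "sim_params"), length(position) == 2)
  e2 <- sum(position^2)
  boost <- if (position[2] < 0) 1 + params$beta_lower else 1
  params$A0 * exp(-e2 / (2 * params$sigma_r^2)) * boost
}

#' Scalp topography weights for a stimulus position
#'
#' Per-channel gain of the evoked signal: a Gaussian bump centered on the
#' occipital pole (so occipital channels always dominate frontal ones),
#' with channels contralateral to the stimulated hemifield scaled by
#' `1 + gamma_contra`. Weights are normalized to a maximum of 1. Midline
#' channels and on-axis stimuli receive no lateral scaling, so mirror-pair
#' weights are equal for on-axis stimuli.
#'
#' @param params A [sim_params()] object.
#' @param montage An [default_montage()] object.
#' @param position Stimulus position `(x, y)` in degrees.
#' @param occipital_tau Width of the occipital Gaussian in montage units.
#' @return Named numeric vector of weights, one per channel, max 1.
#' @export
simulate_topography_weights <- function(params, montage, position,
                                        occipital_tau = 0.6) {
  stopifnot(inherits(params, "sim_params"))
  validate_montage(montage)
  # squared distance to the occipital pole at (0, -1)
  d2 <- montage$x^2 + (montage$y + 1)^2
  w <- exp(-d2 / (2 * occipital_tau^2))
  if (position[1] > 1e-9) {        # right hemifield -> left channels boosted
    w[montage$hemisphere == "L"] <- w[montage$hemisphere == "L"] * (1 + params$gamma_contra)
  } else if (position[1] < -1e-9) { # left hemifield -> right channels boosted
    w[montage$hemisphere == "R"] <- w[montage$hemisphere == "R"] * (1 + params$gamma_contra)
  }
  w <- w / max(w)
  names(w) <- montage$label
  w
}

# 1/f^alpha noise: spectrally shaped white noise, one column per channel,
# each column normalized to unit standard deviation.
pink_noise <- function(n, n_channels, alpha) {
  white <- matrix(stats::rnorm(n * n_channels), n, n_channels)
  if (alpha == 0) return(scale(white, center = FALSE, scale = apply(white, 2, stats::sd)))
  spec <- stats::mvfft(white)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)           # symmetric frequency index; DC at 0
  shape <- c(0, f[-1]^(-alpha / 2))
  spec <- spec * shape
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

#' Simulate one EEG trial epoch
#'
#' Generates a channels x samples epoch as the sum of (i) the evoked
#' response — the position-dependent amplitude times the harmonic series
#' `sum_m decay_m sin(2 pi m f0 t + phi_m)` projected onto the scalp through
#' the topography weights —, (ii) independent 1/f^alpha background noise per
#' channel with standard deviation `1/snr`, and (iii) a common 50 Hz line
#' component with random phase. Time is sampled at `t = 1/fs, 2/fs, ...`,
#' matching the harmonic reference convention, so a noise-free epoch lies
#' exactly in the reference subspace.
#'
#' @param params A [sim_params()] object.
#' @param montage An `eeg_montage`.
#' @param position Stimulus position `(x, y)` in degrees.
#' @param duration_s Epoch duration in seconds.
#' @param fs Sampling rate, Hz.
#' @return Numeric matrix, channels x samples, with channel labels as
#'   row names.
#' @export
simulate_trial_eeg <- function(params, montage, position,
                               duration_s = 4, fs = 500) {
  stopifnot(inherits(params, "sim_params"))
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9) stop("duration_s * fs must be an integer")
  n <- as.integer(round(n))
  t <- seq_len(n) / fs
  amp <- simulate_amplitude(params, position)
  w <- simulate_topography_weights(params, montage, position)
  s <- rep(0, n)
  for (m in seq_len(params$n_harmonics_sim)) {
    s <- s + params$harmonic_decay[m] *
      sin(2 * pi * m * params$f0 * t + params$harmonic_phases[m])
  }
  epoch <- outer(w, amp * s)
  noise_sd <- 1 / params$snr
  if (noise_sd > 0) {
    epoch <- epoch + t(pink_noise(n, nrow(montage), params$noise_alpha)) * noise_sd
  }
  if (params$line_amp > 0) {
    line <- params$line_amp * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
    epoch <- epoch + matrix(line, nrow(montage), n, byrow = TRUE)
  }
  rownames(epoch) <- montage$label
  epoch
}

#' Simulate a gaze trace for one trial
#'
#' Fixation jitter as independent zero-mean Gaussian samples of standard
#' deviation `gaze_sigma` in x and y. With probability `p_excursion` a
#' single contiguous excursion is injected: the gaze ramps out along a
#' random direction to a peak radius drawn from 1.8-3 degrees (beyond the
#' 1.5-degree fixation ring by construction) and back.
#'
#' @param params A [sim_params()] object.
#' @param duration_s Trial duration, seconds.
#' @param fs Gaze sampling rate, Hz.
#' @return Numeric matrix with `duration_s * fs` rows and columns
#'   `x_deg`, `y_deg`.
#' @export
simulate_gaze <- function(params, duration_s = 4, fs = 60) {
  stopifnot(inherits(params, "sim_params"))
  n <- as.integer(round(duration_s * fs))
  g <- cbind(x_deg = stats::rnorm(n, 0, params$gaze_sigma),
             y_deg = stats::rnorm(n, 0, params$gaze_sigma))
  if (params$p_excursion > 0 && stats::runif(1) < params$p_excursion) {
    len <- min(12L, n)
    start <- sample.int(n - len + 1L, 1)
    peak <- stats::runif(1, 1.8, 3)
    theta <- stats::runif(1, 0, 2 * pi)
    ramp <- sin(pi * seq_len(len) / (len + 1))
    ramp <- ramp / max(ramp)            # peak sample reaches exactly `peak`
    idx <- start:(start + len - 1L)
    g[idx, 1] <- peak * ramp * cos(theta)
    g[idx, 2] <- peak * ramp * sin(theta)
  }
  g
}

#' Simulate a complete gaze-restricted session
#'
#' Emulates the repeat-until-success protocol: in each run every stimulus is
#' presented once in random order; a trial attempt whose gaze trace leaves
#' the fixation ring is marked invalid and the trial is re-attempted until
#' it succeeds (up to `max_attempts`), so a completed session has exactly
#' one valid trial per (run, stimulus) pair and retains the failed attempts
#' with `valid = FALSE`.
#'
#' @param params A [sim_params()] object; `params$seed`, when non-NULL,
#'   seeds the session.
#' @param layout An [build_layout()] layout.
#' @param montage An `eeg_montage`.
#' @param n_runs Number of runs.
#' @param duration_s Trial (flicker) duration, seconds.
#' @param fs_eeg EEG sampling rate, Hz.
#' @param fs_gaze Gaze sampling rate, Hz.
#' @param ring_radius Fixation ring radius, degrees.
#' @param max_attempts Retry cap per (run, stimulus); exceeding it aborts
#'   with an error (an unfinishable session).
#' @param participant Participant identifier.
#' @return An object of class `ssvep_session`: a list with `participant`,
#'   `fs_eeg`, `fs_gaze`, `duration_s`, `channels` and `trials`, a list of
#'   trials each holding `run`, `stimulus`, `attempt`, `eeg`
#'   (channels x samples), `gaze` (samples x 2) and `valid`.
#' @export
simulate_session <- function(params, layout, montage,
                             n_runs = 12, duration_s = 4,
                             fs_eeg = 500, fs_gaze = 60,
                             ring_radius = 1.5, max_attempts = 20,
                             participant = "S1") {
  stopifnot(inherits(params, "sim_params"), inherits(layout, "ssvep_layout"))
  validate_montage(montage)
  if (!is.null(params$seed)) set.seed(params$seed)
  n_stim <- nrow(layout$positions)
  trials <- vector("list", 0)
  for (run in seq_len(n_runs)) {
    order <- sample.int(n_stim)
    for (stim in order) {
      pos <- layout$positions[stim, ]
      for (attempt in seq_len(max_attempts + 1L)) {
        if (attempt > max_attempts) {
          stop(sprintf(
            "session unfinishable: stimulus %d in run %d failed %d attempts",
            stim, run, max_attempts))
        }
        gaze <- simulate_gaze(params, duration_s, fs_gaze)
        eeg <- simulate_trial_eeg(params, montage, pos, duration_s, fs_eeg)
        valid <- gate_trial(gaze, ring_radius)
        trials[[length(trials) + 1L]] <- list(
          run = run, stimulus = stim, attempt = attempt,
          eeg = eeg, gaze = gaze, valid = valid)
        if (valid) break
      }
    }
  }
  structure(list(
    participant = participant,
    fs_eeg = fs_eeg, fs_gaze = fs_gaze, duration_s = duration_s,
    channels = montage$label,
    trials = trials
  ), class = "ssvep_session")
}

#' @export
print.ssvep_session <- function(x, ...) {
  valid <- vapply(x$trials, `[[`, logical(1), "valid")
  cat(sprintf(
    "SSVEP session %s: %d trial attempts (%d valid, %d rejected), %d channels at %g Hz\n",
    x$participant, length(x$trials), sum(valid), sum(!valid),
    length(x$channels), x$fs_eeg))
  invisible(x)
}

#' Tabulate the trials of a session
#'
#' @param session An `ssvep_session`.
#' @return Data frame with one row per trial attempt: `run`, `stimulus`,
#'   `attempt`, `valid`.
#' @export
session_trial_table <- function(session) {
  stopifnot(inherits(session, "ssvep_session"))
  data.frame(
    run = vapply(session$trials, `[[`, numeric(1), "run"),
    stimulus = vapply(session$trials, `[[`, numeric(1), "stimulus"),
    attempt = vapply(session$trials, `[[`, numeric(1), "attempt"),
    valid = vapply(session$trials, `[[`, logical(1), "valid")
  )
}
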