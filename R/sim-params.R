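#' Simulation parameters for synthetic SSVEP sessions
#'
#' Bundles the parameters of the forward model used by the session
#' simulator. The defaults encode the qualitative structure the analysis is
#' designed to detect: a 15 Hz fundamental with harmonics, a Gaussian
#' falloff of response amplitude with eccentricity, a boost for stimuli
#' below the horizontal midline, contralateral scalp lateralization,
#' 1/f background activity with 50 Hz line interference, and fixation
#' jitter with occasional excursions beyond the 1.5-degree gaze ring.
#'
#' @param f0 Flicker fundamental frequency, Hz.
#' @param n_harmonics_sim Number of harmonics carried by the evoked signal.
#' @param harmonic_decay Per-harmonic amplitude factors (length
#'   `n_harmonics_sim`); default `1/m` for harmonic `m`.
#' @param harmonic_phases Per-harmonic phases in radians (default all 0,
#'   matching a flicker presented at phase 0).
#' @param A0 Evoked amplitude of the central stimulus, in signal units.
#' @param sigma_r Width (degrees) of the Gaussian eccentricity falloff of
#'   evoked amplitude.
#' @param beta_lower Fractional amplitude boost for stimuli below the
#'   horizontal midline (0.3 means lower-field stimuli evoke 1.3x the
#'   amplitude of the mirror-symmetric upper-field position).
#' @param gamma_contra Fractional gain of scalp channels contralateral to
#'   the stimulated hemifield.
#' @param noise_alpha Spectral exponent of the 1/f^alpha background noise.
#' @param snr Signal-to-noise scale: the background noise standard
#'   deviation per channel is `1/snr` signal units, independent of `A0`
#'   (so `A0 = 0` yields noise-only epochs).
#' @param line_amp Amplitude of the common 50 Hz line component.
#' @param gaze_sigma Standard deviation of fixation jitter, degrees.
#' @param p_excursion Probability per trial attempt of a gaze excursion
#'   crossing the fixation ring.
#' @param seed Optional integer seed applied at the start of
#'   [simulate_session()].
#'
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(f0 = 15,
                       n_harmonics_sim = 3L,
                       harmonic_decay = NULL,
                       harmonic_phases = NULL,
                       A0 = 1,
                       sigma_r = 4,
                       beta_lower = 0.3,
                       gamma_contra = 0.5,
                       noise_alpha = 1,
                       snr = 0.5,
                       line_amp = 0.5,
                       gaze_sigma = 0.3,
                       p_excursion = 0.1,
                       seed = NULL) {
  n_harmonics_sim <- as.integer(n_harmonics_sim)
  if (is.null(harmonic_decay)) harmonic_decay <- 1 / seq_len(n_harmonics_sim)
  if (is.null(harmonic_phases)) harmonic_phases <- rep(0, n_harmonics_sim)
  p <- structure(list(
    f0 = f0, n_harmonics_sim = n_harmonics_sim,
    harmonic_decay = harmonic_decay, harmonic_phases = harmonic_phases,
    A0 = A0, sigma_r = sigma_r, beta_lower = beta_lower,
    gamma_contra = gamma_contra, noise_alpha = noise_alpha, snr = snr,
    line_amp = line_amp, gaze_sigma = gaze_sigma,
    p_excursion = p_excursion, seed = seed
  ), class = "sim_params")
  validate_sim_params(p)
  p
}

#' @rdname sim_params
#' @param params A `sim_params` object.
#' @export
validate_sim_params <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with(params, {
    if (!(f0 > 0)) stop("f0 must be positive")
    if (n_harmonics_sim < 1) stop("need at least one harmonic")
    if (length(harmonic_decay) != n_harmonics_sim ||
        length(harmonic_phases) != n_harmonics_sim) {
      stop("harmonic_decay/harmonic_phases must have one entry per harmonic")
    }
    if (!(sigma_r > 0)) stop("sigma_r must be positive")
    if (p_excursion < 0 || p_excursion > 1) stop("p_excursion must be in [0, 1]")
    if (A0 < 0 || any(harmonic_decay < 0) || line_amp < 0 || gaze_sigma < 0) {
      stop("amplitudes must be non-negative")
    }
    if (!(snr > 0)) stop("snr must be positive")
  })
  invisible(params)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "SSVEP simulation parameters: f0=%g Hz, %d harmonics, A0=%g, sigma_r=%g deg,\n  beta_lower=%g, gamma_contra=%g, snr=%g, gaze_sigma=%g deg, p_excursion=%g\n",
    x$f0, x$n_harmonics_sim, x$A0, x$sigma_r, x$beta_lower, x$gamma_contra,
    x$snr, x$gaze_sigma, x$p_excursion))
  invisible(x)
}
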