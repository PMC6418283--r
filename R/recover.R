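#' Recover the eccentricity-falloff parameters from measured responses
#'
#' Fits the forward model of [simulate_amplitude()] to per-position mean
#' responses. The canonical correlation R is a compressive function of
#' evoked amplitude (it saturates toward 1 for strong responses and has a
#' positive floor for pure noise), so R is first mapped to the amplitude
#' index \eqn{z = R / \sqrt{1 - R^2}}, which for a matched-filter detector
#' is proportional to the signal-to-noise amplitude ratio. The model
#' \deqn{z(e, y) = c + a\,\exp(-e^2/2\sigma_r^2)\,(1 + \beta\,[y < 0])}
#' is then fitted by nonlinear least squares, with `c` absorbing the noise
#' floor.
#'
#' @param means A [position_means()] data frame (participants are pooled by
#'   averaging per stimulus).
#' @param layout An `ssvep_layout`.
#' @return List with the estimates `sigma_r`, `beta`, `a`, `c`, the fitted
#'   `nls` object, and `lower_minus_upper`, the raw difference of mean
#'   responses below versus above the horizontal midline (its sign is the
#'   recovered sign of the lower-field boost).
#' @export
fit_eccentricity_profile <- function(means, layout) {
  agg <- stats::aggregate(mean_r ~ stimulus, data = means, FUN = mean)
  idx <- agg$stimulus
  r <- pmin(agg$mean_r, 1 - 1e-9)
  z <- r / sqrt(1 - r^2)
  e <- sqrt(rowSums(layout$positions[idx, , drop = FALSE]^2))
  lower <- layout$positions[idx, "y"] < 0
  df <- data.frame(z = z, e = e, lower = as.numeric(lower))

  c0 <- min(z)
  a0 <- max(z) - c0
  # half-decay eccentricity as a width start value
  half <- c0 + a0 / 2
  e_half <- suppressWarnings(min(e[z <= half & e > 0], na.rm = TRUE))
  if (!is.finite(e_half)) e_half <- max(e) / 2
  s0 <- max(e_half / sqrt(2 * log(2)), 0.5)

  fit <- stats::nls(
    z ~ cc + a * exp(-e^2 / (2 * sigma^2)) * (1 + beta * lower),
    data = df,
    start = list(cc = c0, a = a0, sigma = s0, beta = 0),
    algorithm = "port",
    lower = c(cc = 0, a = 1e-6, sigma = 0.1, beta = -0.9),
    upper = c(cc = Inf, a = Inf, sigma = 100, beta = 5),
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  est <- stats::coef(fit)

  lmu <- mean(agg$mean_r[lower]) - mean(agg$mean_r[!lower])
  list(sigma_r = unname(est["sigma"]), beta = unname(est["beta"]),
       a = unname(est["a"]), c = unname(est["cc"]),
       fit = fit, lower_minus_upper = lmu)
}
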