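#' Harmonic sine/cosine reference set
#'
#' Builds the reference matrix used for canonical-correlation scoring of an
#' SSVEP epoch: for each harmonic m = 1..M of the stimulation frequency f,
#' a sine and a cosine row evaluated at t = 1/S, 2/S, ..., N/S (note the
#' time base starts at 1/S, not 0):
#' \deqn{Y_f = [\sin(2\pi f t); \cos(2\pi f t); \ldots;
#'             \sin(2\pi M f t); \cos(2\pi M f t)].}
#'
#' @param f Stimulation frequency, Hz.
#' @param M Number of harmonics.
#' @param S Sampling rate, Hz.
#' @param N Number of samples.
#' @return A 2M x N numeric matrix of class `ssvep_reference` with
#'   attributes `f`, `M`, `S`, `N`; rows alternate sin, cos per harmonic.
#' @examples
#' Y <- build_reference(15, 3, 500, 2000)
#' dim(Y)  # 6 2000
#' @export
build_reference <- function(f, M, S, N) {
  stopifnot(f > 0, M >= 1, S > 0, N >= 2 * M)
  M <- as.integer(M)
  if (M * f >= S / 2) {
    stop(sprintf("aliasing: harmonic %d x %g Hz = %g Hz reaches Nyquist (%g Hz)",
                 M, f, M * f, S / 2))
  }
  t <- seq_len(N) / S
  Y <- matrix(0, 2 * M, N)
  for (m in seq_len(M)) {
    Y[2 * m - 1, ] <- sin(2 * pi * m * f * t)
    Y[2 * m, ]     <- cos(2 * pi * m * f * t)
  }
  rownames(Y) <- paste0(rep(c("sin", "cos"), M), rep(seq_len(M), each = 2), "f")
  structure(Y, f = f, M = M, S = S, N = N,
            class = c("ssvep_reference", "matrix", "array"))
}

# Largest canonical correlation from the covariance triple, by singular
# decomposition of the whitened cross-covariance. Whitening uses an
# eigen-decomposition with a relative tolerance so rank-deficient (e.g.
# noise-free) inputs are handled exactly rather than ridged.
.cca_from_cov <- function(Cxx, Cxy, Cyy, tol = 1e-10, want_weights = FALSE) {
  ex <- eigen(Cxx, symmetric = TRUE)
  ey <- eigen(Cyy, symmetric = TRUE)
  kx <- ex$values > max(ex$values[1], 0) * tol
  ky <- ey$values > max(ey$values[1], 0) * tol
  if (!any(kx) || !any(ky)) {
    return(list(R = 0, w_x = NULL, w_y = NULL, degenerate = TRUE))
  }
  Wxh <- ex$vectors[, kx, drop = FALSE] %*%
    diag(1 / sqrt(ex$values[kx]), sum(kx))
  Wyh <- ey$vectors[, ky, drop = FALSE] %*%
    diag(1 / sqrt(ey$values[ky]), sum(ky))
  Tm <- crossprod(Wxh, Cxy %*% Wyh)
  sv <- svd(Tm)
  R <- min(max(sv$d[1], 0), 1)
  out <- list(R = R, w_x = NULL, w_y = NULL, degenerate = FALSE)
  if (want_weights) {
    w_x <- drop(Wxh %*% sv$u[, 1])
    w_y <- drop(Wyh %*% sv$v[, 1])
    nz <- which(abs(w_x) > 1e-12)[1]
    if (!is.na(nz) && w_x[nz] < 0) {
      w_x <- -w_x
      w_y <- -w_y
    }
    out$w_x <- w_x
    out$w_y <- w_y
  }
  out
}

#' Canonical correlation between an epoch and a harmonic reference
#'
#' Computes the SSVEP response of a multichannel epoch as the largest
#' canonical correlation R between the channel space of `X` and the span of
#' the harmonic reference `Y`, maximized over weight vectors on both sides.
#' Rows of both matrices are mean-centered internally. R lies in [0, 1] and
#' is invariant to channel permutation, per-channel affine rescaling, and
#' sign flips; adding a channel can never decrease it.
#'
#' Rank-deficient inputs (collinear or zero-variance channels) are handled
#' by whitening on the numerically nonzero eigen-directions only; a
#' zero-variance channel raises a warning and an all-zero `X` yields R = 0
#' with a warning.
#'
#' @param X Numeric matrix, channels x samples (a vector is treated as one
#'   channel).
#' @param Y A [build_reference()] matrix (or any reference matrix,
#'   rows x samples).
#' @return An object of class `cca_result`: list with `R`, `w_x`, `w_y`,
#'   `channels`.
#' @export
cca_coefficient <- function(X, Y) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  Y <- unclass(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same number of samples")
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  v <- rowSums(Xc^2) / n
  if (any(v <= .Machine$double.eps * 100)) {
    if (all(v <= .Machine$double.eps * 100)) {
      warning("all channels have zero variance; R defined as 0")
      return(structure(list(R = 0, w_x = rep(0, nrow(X)),
                            w_y = rep(0, nrow(Y)), channels = rownames(X)),
                       class = "cca_result"))
    }
    warning("zero-variance channel(s) present; excluded by rank truncation")
  }
  Cxx <- tcrossprod(Xc) / n
  Cyy <- tcrossprod(Yc) / n
  Cxy <- tcrossprod(Xc, Yc) / n
  res <- .cca_from_cov(Cxx, Cxy, Cyy, want_weights = TRUE)
  structure(list(R = res$R, w_x = res$w_x, w_y = res$w_y,
                 channels = rownames(X)),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("CCA result: R = %.6f (%d channel(s))\n", x$R,
              if (is.null(x$channels)) length(x$w_x) else length(x$channels)))
  invisible(x)
}

#' Single-channel SSVEP response
#'
#' The canonical correlation of one channel against the harmonic reference
#' ([cca_coefficient()] with a one-row `X`).
#'
#' @param epoch Channels x samples matrix with channel labels as row names.
#' @param channel Channel label or row index.
#' @param Y Reference matrix.
#' @return Numeric scalar R.
#' @export
single_channel_response <- function(epoch, channel, Y) {
  if (is.character(channel)) {
    channel <- match(channel, rownames(epoch))
    if (is.na(channel)) stop("unknown channel label")
  }
  cca_coefficient(epoch[channel, , drop = FALSE], Y)$R
}
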