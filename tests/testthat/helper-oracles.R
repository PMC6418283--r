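# Independent oracles, deliberately implemented through different numerical
# routes than the package (generalized eigenvalue problem, projections,
# permutation tests). Written against the definitions, not the package code.

# largest canonical correlation via the generalized eigenvalue problem
# inv(Cxx) Cxy inv(Cyy) Cyx, solved with plain solve()/eigen()
cca_oracle_gev <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  Cxx <- tcrossprod(Xc) / n
  Cyy <- tcrossprod(Yc) / n
  Cxy <- tcrossprod(Xc, Yc) / n
  Mm <- solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy))
  sqrt(max(0, max(Re(eigen(Mm, only.values = TRUE)$values))))
}

# canonical correlation of a single channel: norm of the projection of the
# centered channel onto the span of the centered reference rows
single_cca_oracle <- function(x, Y) {
  x <- x - mean(x)
  Yc <- t(as.matrix(Y)) # samples x rows
  Yc <- sweep(Yc, 2, colMeans(Yc))
  proj <- Yc %*% solve(crossprod(Yc), crossprod(Yc, x))
  sqrt(sum(proj^2) / sum(x^2))
}

# two-sided permutation test for a difference in means
perm_ttest_oracle <- function(g1, g2, B = 2000, seed = 42) {
  set.seed(seed)
  obs <- abs(mean(g1) - mean(g2))
  pool <- c(g1, g2)
  n1 <- length(g1)
  stat <- replicate(B, {
    idx <- sample(length(pool), n1)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  (1 + sum(stat >= obs - 1e-12)) / (B + 1)
}

# permutation distribution of the Kruskal-Wallis H statistic (two groups)
perm_kw_oracle <- function(g1, g2, B = 2000, seed = 42) {
  set.seed(seed)
  kw_h <- function(x, grp) {
    r <- rank(x)
    n <- length(x)
    tie <- table(r)
    correction <- 1 - sum(tie^3 - tie) / (n^3 - n)
    h <- 12 / (n * (n + 1)) *
      sum(tapply(r, grp, function(v) length(v) * mean(v)^2)) - 3 * (n + 1)
    h / correction
  }
  x <- c(g1, g2)
  grp <- rep(1:2, c(length(g1), length(g2)))
  obs <- kw_h(x, grp)
  stat <- replicate(B, kw_h(x, sample(grp)))
  (1 + sum(stat >= obs - 1e-12)) / (B + 1)
}

# 1/f-shaped noise generated directly in the test (independent of the
# package's generator) for null-distribution draws
oracle_pink_noise <- function(n, alpha = 1) {
  spec <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k)
  spec <- spec * c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}
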