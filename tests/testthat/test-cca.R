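test_that("harmonic reference matches its closed-form definition", {
  Y <- build_reference(15, 3, 500, 2000)
  expect_equal(dim(Y), c(6L, 2000L))
  t <- seq_len(2000) / 500
  # rows alternate sin/cos at 15, 30, 45 Hz; time base starts at 1/S
  expect_equal(Y[1, ], sin(2 * pi * 15 * t), ignore_attr = TRUE)
  expect_equal(Y[2, ], cos(2 * pi * 15 * t), ignore_attr = TRUE)
  expect_equal(Y[5, ], sin(2 * pi * 45 * t), ignore_attr = TRUE)
  expect_equal(unname(Y[1, 1]), sin(2 * pi * 15 / 500))
  expect_equal(unname(Y[2, 1]), cos(2 * pi * 15 / 500))
  # aliasing guard at the Nyquist frequency
  expect_error(build_reference(50, 5, 500, 2000), "Nyquist")
  expect_error(build_reference(15, 3, 500, 4), "N")
})

test_that("R is exact on in-span and orthogonal signals", {
  Y <- build_reference(15, 3, 500, 2000)
  t <- seq_len(2000) / 500
  expect_equal(cca_coefficient(sin(2 * pi * 15 * t), Y)$R, 1,
               tolerance = 1e-9)
  # harmonic mixture also lies in the span
  mix <- sin(2 * pi * 15 * t + 0.7) + 0.3 * sin(2 * pi * 30 * t + 1.1)
  expect_equal(cca_coefficient(mix, Y)$R, 1, tolerance = 1e-9)
  # a 7 Hz tone over an integer number of cycles is orthogonal to the bank
  expect_lt(cca_coefficient(sin(2 * pi * 7 * t), Y)$R, 1e-6)
})

test_that("R matches the generalized-eigenvalue oracle and stats::cancor", {
  Y <- build_reference(10, 2, 100, 200)
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(3 * 200), 3, 200)
    r <- cca_coefficient(X, Y)$R
    expect_equal(r, cca_oracle_gev(X, unclass(Y)), tolerance = 1e-8)
    expect_equal(r, stats::cancor(t(X), t(unclass(Y)))$cor[1],
                 tolerance = 1e-8)
  }
})

test_that("R is invariant to permutation, affine rescaling and sign flips", {
  Y <- build_reference(10, 2, 100, 200)
  set.seed(71)
  X <- matrix(rnorm(4 * 200), 4, 200)
  r <- cca_coefficient(X, Y)$R
  expect_equal(cca_coefficient(X[c(3, 1, 4, 2), ], Y)$R, r, tolerance = 1e-10)
  Xs <- X * c(2.5, -1, 0.01, 7) + c(10, -3, 0, 100)
  expect_equal(cca_coefficient(Xs, Y)$R, r, tolerance = 1e-9)
  expect_equal(cca_coefficient(-X, Y)$R, r, tolerance = 1e-10)
})

test_that("adding a channel never decreases R (nesting property)", {
  Y <- build_reference(10, 2, 100, 200)
  for (seed in 1:10) {
    set.seed(100 + seed)
    X <- matrix(rnorm(5 * 200), 5, 200)
    rs <- vapply(1:5, function(k) {
      cca_coefficient(X[1:k, , drop = FALSE], Y)$R
    }, numeric(1))
    expect_true(all(diff(rs) >= -1e-10))
  }
})

test_that("single-channel responses: identity, duplication, null level", {
  Y <- build_reference(15, 3, 500, 2000)
  t <- seq_len(2000) / 500
  X <- rbind(fund = sin(2 * pi * 15 * t), noise = rnorm(2000))
  expect_equal(single_channel_response(X, "fund", Y), 1, tolerance = 1e-9)
  # duplicated channel: identical R (scale invariance)
  set.seed(72)
  ch <- rnorm(2000)
  X2 <- rbind(a = ch, b = 3 * ch + 2)
  expect_equal(single_channel_response(X2, "a", Y),
               single_channel_response(X2, "b", Y), tolerance = 1e-10)
  # a white-noise channel stays below the 99th percentile of the null,
  # estimated with the independent projection oracle
  set.seed(73)
  null <- replicate(500, single_cca_oracle(rnorm(2000), unclass(Y)))
  q99 <- stats::quantile(null, 0.99)
  set.seed(74)
  expect_lt(single_channel_response(matrix(rnorm(2000), 1), 1, Y), q99)
  # the oracle and the implementation agree on single channels
  set.seed(75)
  x <- rnorm(2000)
  expect_equal(cca_coefficient(x, Y)$R, single_cca_oracle(x, unclass(Y)),
               tolerance = 1e-8)
})

test_that("degenerate inputs are handled with warnings", {
  Y <- build_reference(10, 2, 100, 200)
  set.seed(76)
  X <- rbind(rnorm(200), rep(1, 200))  # one flat channel
  expect_warning(r <- cca_coefficient(X, Y), "zero-variance")
  expect_true(r$R >= 0 && r$R <= 1)
  expect_warning(r0 <- cca_coefficient(matrix(0, 2, 200), Y), "zero")
  expect_equal(r0$R, 0)
})
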