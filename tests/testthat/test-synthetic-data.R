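test_that("evoked amplitude follows the Gaussian-falloff forward model", {
  p <- sim_params()
  expect_equal(simulate_amplitude(p, c(0, 0)), p$A0)
  # lower-field boost is a pure factor
  expect_equal(simulate_amplitude(p, c(3, -1)) / simulate_amplitude(p, c(3, 1)),
               1 + p$beta_lower)
  # half-maximum eccentricity of the Gaussian (upper field: no boost)
  e_half <- p$sigma_r * sqrt(2 * log(2))
  expect_equal(simulate_amplitude(p, c(0, e_half)), p$A0 / 2)
  # amplitude is monotone decreasing in eccentricity within a half-field
  eccs <- seq(0.5, 10, by = 0.5)
  amps <- vapply(eccs, function(e) simulate_amplitude(p, c(e, 1e-6)), 1)
  expect_true(all(diff(amps) < 0))
})

test_that("scalp weights are occipital, mirror-symmetric and contralateral", {
  p <- sim_params()
  m <- default_mont
  pairs <- attr(m, "pairs")
  # on-axis stimulus: mirror-pair weights equal
  w0 <- simulate_topography_weights(p, m, c(0, 0))
  for (pr in pairs) expect_equal(w0[pr[1]], w0[pr[2]], ignore_attr = TRUE)
  # right-hemifield stimulus: left channel of each pair gains (1 + gamma)
  wr <- simulate_topography_weights(p, m, c(4, 1))
  for (pr in pairs) {
    expect_equal(wr[pr[1]] / wr[pr[2]], 1 + p$gamma_contra,
                 ignore_attr = TRUE)
  }
  # frontal channels always receive less than occipital channels
  frontal <- c("Fp1", "Fp2", "F3", "Fz", "F4")
  occipital <- c("O1", "Oz", "O2")
  for (i in seq_len(nrow(default_layout$positions))) {
    w <- simulate_topography_weights(p, m, default_layout$positions[i, ])
    expect_lt(max(w[frontal]), min(w[occipital]))
  }
})

test_that("noise-free epochs live exactly in the reference subspace", {
  p <- noise_free_params()
  e <- simulate_trial_eeg(p, default_mont, c(0, 0))
  Y <- build_reference(15, 3, 500, ncol(e))
  expect_equal(cca_coefficient(e[op_subset, ], Y)$R, 1, tolerance = 1e-9)
  # every single channel too
  expect_equal(single_channel_response(e, "Oz", Y), 1, tolerance = 1e-9)
})

test_that("trial EEG is reproducible under a fixed seed", {
  p <- sim_params()
  set.seed(11); e1 <- simulate_trial_eeg(p, default_mont, c(2, -1))
  set.seed(11); e2 <- simulate_trial_eeg(p, default_mont, c(2, -1))
  expect_identical(e1, e2)
  set.seed(12); e3 <- simulate_trial_eeg(p, default_mont, c(2, -1))
  expect_false(identical(e1, e3))
})

test_that("A0 = 0 epochs score at the noise-only null level", {
  p <- sim_params(A0 = 0, line_amp = 0)
  Y <- build_reference(15, 3, 500, 2000)
  set.seed(21)
  r_sim <- replicate(100, {
    e <- simulate_trial_eeg(p, default_mont, c(0, 0))
    cca_coefficient(e[op_subset, ], Y)$R
  })
  # independent null: 11 channels of 1/f noise generated by the oracle
  set.seed(22)
  r_null <- replicate(200, {
    X <- t(vapply(1:11, function(i) oracle_pink_noise(2000), numeric(2000)))
    cca_coefficient(X, Y)$R
  })
  se <- sqrt(stats::var(r_sim) / 100 + stats::var(r_null) / 200)
  expect_lt(abs(mean(r_sim) - mean(r_null)), 4 * se)
})

test_that("gaze traces obey the jitter and excursion contract", {
  p0 <- sim_params(gaze_sigma = 0, p_excursion = 0)
  g <- simulate_gaze(p0)
  expect_equal(nrow(g), 240L)
  expect_true(all(g == 0))
  # guaranteed excursion always fails the ring test
  p1 <- sim_params(p_excursion = 1)
  set.seed(31)
  for (i in 1:20) expect_false(gate_trial(simulate_gaze(p1), 1.5))
  # determinism
  set.seed(32); g1 <- simulate_gaze(sim_params())
  set.seed(32); g2 <- simulate_gaze(sim_params())
  expect_identical(g1, g2)
})

test_that("sessions complete with exactly one valid trial per (run, stimulus)", {
  small <- build_layout(ring_counts = c(3))
  # zero excursions: no retries at all
  s0 <- simulate_session(sim_params(p_excursion = 0, seed = 41), small,
                         default_mont, n_runs = 2)
  tt0 <- session_trial_table(s0)
  expect_equal(nrow(tt0), 8L)
  expect_true(all(tt0$valid))
  # excursions force retries, but completion still holds
  s1 <- simulate_session(sim_params(p_excursion = 0.5, seed = 42), small,
                         default_mont, n_runs = 3)
  tt1 <- session_trial_table(s1)
  expect_gt(sum(!tt1$valid), 0)
  per_pair <- aggregate(valid ~ run + stimulus, data = tt1, FUN = sum)
  expect_true(all(per_pair$valid == 1L))
  # every stimulus ends with one valid trial per run
  valid_counts <- table(tt1$stimulus[tt1$valid])
  expect_true(all(valid_counts == 3L))
  # an unfinishable session errors at the retry cap
  expect_error(
    simulate_session(sim_params(p_excursion = 1, seed = 43), small,
                     default_mont, n_runs = 1, max_attempts = 5),
    "unfinishable")
})

test_that("raising snr never lowers the central-stimulus response", {
  Y <- build_reference(15, 3, 500, 2000)
  means <- vapply(c(0.25, 0.5, 1), function(snr) {
    set.seed(51)
    mean(replicate(6, {
      e <- simulate_trial_eeg(sim_params(snr = snr), default_mont, c(0, 0))
      cca_coefficient(e[op_subset, ], Y)$R
    }))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})
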