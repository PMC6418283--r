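test_that("leave-one-out contribution of a duplicated channel is zero", {
  Y <- build_reference(15, 3, 500, 2000)
  t <- seq_len(2000) / 500
  set.seed(91)
  sig <- sin(2 * pi * 15 * t) + 0.5 * rnorm(2000)
  X <- rbind(a = sig, b = sig, c = rnorm(2000))
  expect_equal(channel_contribution(X, Y, "a"), 0, tolerance = 1e-9)
  expect_equal(channel_contribution(X, Y, "b"), 0, tolerance = 1e-9)
})

test_that("contribution matches two independent oracle CCA runs", {
  Y <- build_reference(15, 3, 500, 1000)
  t <- seq_len(1000) / 500
  set.seed(92)
  X <- rbind(sin(2 * pi * 15 * t) + 0.3 * rnorm(1000),
             rnorm(1000), rnorm(1000))
  r_all <- cca_oracle_gev(X, unclass(Y))
  r_wo <- cca_oracle_gev(X[-1, ], unclass(Y))
  expect_equal(channel_contribution(X, Y, 1), (r_all - r_wo) / r_all,
               tolerance = 1e-8)
  # contributions are bounded above by 1
  for (ch in 1:3) expect_lte(channel_contribution(X, Y, ch), 1)
})

test_that("pure-noise contributions are small and sit at the null bias", {
  Y <- build_reference(15, 3, 500, 500)
  set.seed(93)
  vals <- replicate(200, {
    X <- matrix(rnorm(4 * 500), 4, 500)
    channel_contribution(X, Y, 1)
  })
  # under the null the contribution is not exactly zero-mean: dropping a
  # channel lowers the overfitted null R, giving a small positive bias of
  # about 1 - E[R_{C-1}]/E[R_C]; estimate that independently
  set.seed(193)
  r4 <- r3 <- numeric(200)
  for (i in 1:200) {
    X <- matrix(rnorm(4 * 500), 4, 500)
    r4[i] <- cca_oracle_gev(X, unclass(Y))
    r3[i] <- cca_oracle_gev(X[-1, ], unclass(Y))
  }
  pred_bias <- 1 - mean(r3) / mean(r4)
  expect_lt(abs(mean(vals) - pred_bias), 0.03)
  expect_lt(max(abs(vals)), 0.9)
  expect_lt(stats::sd(vals), 0.15)
})

test_that("contribution maps localize to occipital and contralateral sites", {
  small <- build_layout(ring_counts = c(3))
  occ <- c("O1", "Oz", "O2", "POz")
  for (seed in 1:3) {
    s <- simulate_session(sim_params(seed = seed, p_excursion = 0), small,
                          default_mont, n_runs = 1)
    cm <- contribution_map(s)
    # central stimulus: strongest contribution at an occipital site
    expect_true(rownames(cm)[which.max(cm[, "1"])] %in% occ)
    # right-hemifield stimuli: left pair members dominate at PO3-PO4
    cls <- vapply(2:4, function(i) classify_position(small, i)$hemifield, "")
    right_stim <- as.character(which(c("on", cls) == "right"))
    expect_gt(mean(cm["PO3", right_stim]), mean(cm["PO4", right_stim]))
  }
})

test_that("contralateral scores follow their closed-form toy values", {
  L <- default_layout
  pair <- c("PO3", "PO4")
  idx_all <- seq_len(nrow(L$positions))
  base <- data.frame(participant = "P1",
                     stimulus = rep(idx_all, each = 2),
                     channel = rep(pair, length(idx_all)),
                     r = 0.4)
  # all responses equal to the central response: both terms are 1, E = 0
  expect_equal(contralateral_score(base, L, "right", 10, pair), 0)
  # mirror-symmetric responses cancel exactly
  sym <- base
  sym$r <- ifelse(sym$channel == "PO3", 0.6, 0.6)
  expect_equal(contralateral_score(sym, L, "left", 6, pair), 0)
  # left channel at 1.5x reference, right at 0.5x: E = 1.5 - 0.5 = 1
  toy <- base
  toy$r[toy$stimulus != 1 & toy$channel == "PO3"] <- 0.6
  toy$r[toy$stimulus != 1 & toy$channel == "PO4"] <- 0.2
  expect_equal(contralateral_score(toy, L, "right", 10, pair), 1)
  # swapping the pair negates the score exactly
  set.seed(94)
  noisy <- base
  noisy$r <- runif(nrow(noisy), 0.1, 0.9)
  noisy$r[noisy$stimulus == 1] <- 0.5
  e <- contralateral_score(noisy, L, "right", 6, pair)
  expect_equal(contralateral_score(noisy, L, "right", 6, rev(pair)), -e)
  # zero central reference is an error
  bad <- base; bad$r[bad$stimulus == 1] <- 0
  expect_error(contralateral_score(bad, L, "right", 6, pair), "reference")
  # no qualifying stimulus: missing value (single-layer variant, angle with
  # no ring)
  expect_true(is.na(contralateral_score(base, L, "right", 3, pair,
                                        within = "layer")))
})

test_that("Kruskal-Wallis pair comparison: ties, identity, oracle", {
  # identical groups: all tied
  kw0 <- kw_significance(rep(1, 5), rep(1, 5))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)
  expect_false(kw0$significant)
  # same multiset in both groups: far from significance
  kw1 <- kw_significance(c(1, 2, 3), c(1, 2, 3))
  expect_gt(kw1$p, 0.9)
  expect_false(kw1$significant)
  # well-separated groups: significant, and the permutation oracle agrees
  set.seed(95)
  g1 <- rnorm(12, 1.0, 0.1)
  g2 <- rnorm(12, 0.4, 0.1)
  kw2 <- kw_significance(g1, g2)
  expect_true(kw2$significant)
  expect_lt(perm_kw_oracle(g1, g2), 0.05)
})

test_that("simulated sessions reproduce the contralateral sign pattern", {
  fa <- full_analysis(1)
  ct <- contralateral_table(fa$sc, default_layout)
  for (pr in c("PO3-PO4", "P3-P4")) {
    sub <- ct[ct$pair == pr, ]
    expect_true(all(sub$score[sub$side == "right"] > 0))
    expect_true(all(sub$score[sub$side == "left"] < 0))
  }
})
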