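test_that("position means average valid trials and flag missing stimuli", {
  rt <- make_rt(data.frame(run = 1:12, stimulus = 1, r = 0.5))
  expect_equal(position_mean_response(rt, "P1", 1), 0.5)
  rt2 <- make_rt(data.frame(run = 1:2, stimulus = 1, r = c(0.2, 0.4)))
  expect_equal(position_mean_response(rt2, "P1", 1), 0.3)
  expect_warning(v <- position_mean_response(rt2, "P1", 2), "no valid trials")
  expect_true(is.na(v))
})

test_that("layer averages reduce stimuli then participants", {
  L <- default_layout
  rt <- uniform_rt(L, n_runs = 2, base = 0.4, central = 0.4)
  la <- layer_average(rt, L)
  expect_equal(unname(la), rep(0.4, 6))
  # layer 1 mean is the central-stimulus mean
  rt2 <- uniform_rt(L, n_runs = 3, base = 0.2, central = 0.9)
  la2 <- layer_average(rt2, L)
  expect_equal(unname(la2[1]), 0.9)
  expect_equal(unname(la2[-1]), rep(0.2, 5))
  # two participants are weighted equally regardless of trial counts
  rt3 <- rbind(uniform_rt(L, 1, base = 0, central = 0, participant = "A"),
               uniform_rt(L, 3, base = 1, central = 1, participant = "B"))
  class(rt3) <- c("response_table", "data.frame")
  expect_equal(unname(layer_average(rt3, L)), rep(0.5, 6))
})

test_that("simulated responses decrease with eccentricity layer by layer", {
  la <- full_analysis(1)$layers
  expect_length(la, 6L)
  expect_true(all(diff(la) < 0))
})

test_that("run-wise error rates reproduce the 1/12 and 1/11 lattices", {
  L <- default_layout
  # one exceedance among 12 runs: a single layer-2 stimulus beats the center
  over <- data.frame(run = 5, stimulus = stimuli_in_layer(L, 2)[1], r = 0.9)
  rt <- uniform_rt(L, n_runs = 12, base = 0.2, central = 0.8, overrides = over)
  er <- error_rate(rt, L, "P1", 2)
  expect_equal(er$rate, 100 / 12)
  expect_equal(er$n_runs_used, 12L)
  # no exceedance anywhere
  er0 <- error_rate(uniform_rt(L, 12), L, "P1", 4)
  expect_equal(er0$rate, 0)
  # one run unusable (missing central trial) -> denominator 11
  rt11 <- rt[!(rt$run == 12 & rt$stimulus == 1), ]
  class(rt11) <- c("response_table", "data.frame")
  er11 <- error_rate(rt11, L, "P1", 2)
  expect_equal(er11$n_runs_used, 11L)
  expect_equal(er11$rate, 100 / 11, tolerance = 1e-9)
  expect_equal(round(er11$rate, 2), 9.09)
})

test_that("error rates are invariant under monotone transforms of a run", {
  L <- default_layout
  set.seed(81)
  vals <- expand.grid(run = 1:6, stimulus = seq_len(nrow(L$positions)))
  vals$r <- runif(nrow(vals), 0.1, 0.9)
  rt <- make_rt(vals)
  base <- vapply(c(2, 4, 6, 8, 10),
                 function(d) error_rate(rt, L, "P1", d)$rate, numeric(1))
  # strictly monotone map applied to every response
  rt2 <- rt; rt2$r <- exp(3 * rt2$r) - 0.5
  trans <- vapply(c(2, 4, 6, 8, 10),
                  function(d) error_rate(rt2, L, "P1", d)$rate, numeric(1))
  expect_equal(trans, base)
})

test_that("published per-participant rates average to the reported AVE row", {
  ref <- reference_error_rates()
  ave <- average_error_rates(ref[, -1])
  expect_equal(unname(ave), c(11.55, 5.30, 2.08, 2.08, 2.08))
  # identical rates across participants average to themselves
  flat <- matrix(8.33, 3, 5)
  expect_equal(unname(average_error_rates(flat)), rep(8.33, 5))
})

test_that("central-vs-peripheral t-test: degenerate, separated, symmetric", {
  L <- default_layout
  rt <- uniform_rt(L, n_runs = 12, base = 0.2, central = 0.8)
  # identical values in both groups: degenerate convention p = 1 needs
  # equal means; here means differ with zero variance -> p -> 0
  expect_warning(p0 <- central_peripheral_ttest(rt, L, "P1", 2), "variance")
  expect_equal(p0, 0)
  rt_eq <- uniform_rt(L, n_runs = 12, base = 0.5, central = 0.5)
  expect_warning(p1 <- central_peripheral_ttest(rt_eq, L, "P1", 2), "variance")
  expect_equal(p1, 1)
  # well-separated noisy groups
  set.seed(82)
  vals <- expand.grid(run = 1:12, stimulus = seq_len(nrow(L$positions)))
  vals$r <- ifelse(vals$stimulus == 1, rnorm(nrow(vals), 0.8, 0.01),
                   rnorm(nrow(vals), 0.2, 0.01))
  rt2 <- make_rt(vals)
  p <- central_peripheral_ttest(rt2, L, "P1", 4)
  expect_lt(p, 0.001)
  # permutation oracle agrees that the difference is extreme
  g1 <- rt2$r[rt2$stimulus == 1]
  g2 <- rt2$r[rt2$stimulus %in% stimuli_in_layer(L, 3)]
  expect_lt(perm_ttest_oracle(g1, g2), 0.001)
  # two-sided symmetry under group swap
  vals_sw <- vals
  vals_sw$r <- ifelse(vals$stimulus == 1, 1 - vals$r, 1 - vals$r)
  rt_sw <- make_rt(vals_sw)
  expect_equal(central_peripheral_ttest(rt_sw, L, "P1", 4), p,
               tolerance = 1e-12)
})

test_that("error-rate table carries per-participant rows and an AVE row", {
  L <- default_layout
  over <- data.frame(run = 1, stimulus = stimuli_in_layer(L, 2)[1], r = 0.9)
  rt <- rbind(
    uniform_rt(L, 12, base = 0.2, central = 0.8, overrides = over,
               participant = "A"),
    uniform_rt(L, 12, base = 0.2, central = 0.8, participant = "B"))
  class(rt) <- c("response_table", "data.frame")
  set.seed(83)
  rt$r <- rt$r + rnorm(nrow(rt), 0, 1e-4)  # avoid degenerate variance
  tab <- suppressWarnings(error_rate_table(rt, L))
  expect_equal(nrow(tab), 15L)  # 2 participants x 5 angles + AVE x 5
  a2 <- tab$rate[tab$participant == "A" & tab$angle == 2]
  expect_equal(a2, 100 / 12, tolerance = 0.01)
  ave2 <- tab$rate[tab$participant == "AVE" & tab$angle == 2]
  expect_equal(ave2, round(mean(tab$rate[tab$participant != "AVE" &
                                           tab$angle == 2]), 2))
})

test_that("surface interpolation is exact at nodes, flat and linear", {
  L <- default_layout
  set.seed(84)
  vals <- stats::setNames(runif(46, 0.2, 0.9), 1:46)
  g <- surface_grid(vals, L, grid_resolution = 41)
  # node exactness, via point interpolation at the stimulus coordinates
  # (the co-circular rings force a jittered triangulation, hence ~1e-6)
  # outer-ring nodes sit on the hull boundary and may fall outside the
  # jittered triangulation; check the interior nodes (layers 1-5)
  inner <- which(L$layer <= 5)
  chk <- suppressWarnings(
    interp::interp(L$positions[, "x"], L$positions[, "y"],
                   as.numeric(vals),
                   xo = L$positions[inner, "x"], yo = L$positions[inner, "y"],
                   output = "points", method = "linear"))
  expect_false(anyNA(chk$z))
  expect_lt(max(abs(chk$z - as.numeric(vals)[inner])), 1e-4)
  # a uniform map interpolates to a flat surface inside the hull
  gu <- surface_grid(stats::setNames(rep(0.5, 46), 1:46), L,
                     grid_resolution = 31)
  expect_equal(range(gu$z, na.rm = TRUE), c(0.5, 0.5), tolerance = 1e-6)
  # outside the convex hull the surface is undefined
  expect_true(anyNA(gu$z))
  # degenerate (collinear) geometry errors
  L2 <- build_layout(ring_counts = c(2))
  expect_error(surface_grid(stats::setNames(c(1, 2, 3), 1:3), L2),
               "degenerate|collinear")
})
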