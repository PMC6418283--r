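# Shared fixtures. Sessions are expensive, so full-protocol analyses used by
# several acceptance checks are cached per seed within the test run.

.fixture_cache <- new.env(parent = emptyenv())

default_layout <- build_layout()
default_mont <- default_montage()
op_subset <- attr(default_mont, "analysis_subset")

# noise-free parameters: evoked signal only
noise_free_params <- function(...) {
  p <- sim_params(line_amp = 0, gaze_sigma = 0, p_excursion = 0, ...)
  p$snr <- Inf
  p
}

# a small but complete session: full 46-stimulus layout, few runs
quick_session <- function(seed, n_runs = 2, ...) {
  simulate_session(sim_params(seed = seed, ...), default_layout, default_mont,
                   n_runs = n_runs)
}

# full-protocol analysis for one simulated participant (12 runs, gaze gating,
# zero-phase filtering, CCA scoring); cached by seed
full_analysis <- function(seed) {
  key <- paste0("seed", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  s <- simulate_session(sim_params(seed = seed), default_layout, default_mont,
                        n_runs = 12, participant = paste0("S", seed))
  s <- gate_session(s)
  s <- preprocess_session(s)
  rt <- response_table(s)
  res <- list(
    rt = rt,
    pm = position_means(rt),
    layers = layer_average(rt, default_layout),
    sc = single_channel_table(s)
  )
  .fixture_cache[[key]] <- res
  res
}

# hand-built response table: one participant, given per-(run, stimulus) values
make_rt <- function(values, participant = "P1") {
  # values: data.frame(run, stimulus, r)
  df <- data.frame(participant = participant, run = values$run,
                   stimulus = values$stimulus, r = values$r)
  class(df) <- c("response_table", "data.frame")
  df
}

# response table where every (run, stimulus) has a constant value, with
# selected overrides
uniform_rt <- function(layout, n_runs, base = 0.2, central = 0.8,
                       overrides = NULL, participant = "P1") {
  n_stim <- nrow(layout$positions)
  df <- expand.grid(run = seq_len(n_runs), stimulus = seq_len(n_stim))
  df$r <- ifelse(df$stimulus == 1, central, base)
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      sel <- df$run == overrides$run[i] & df$stimulus == overrides$stimulus[i]
      df$r[sel] <- overrides$r[i]
    }
  }
  make_rt(df, participant)
}
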