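#' Pipeline configuration
#'
#' Collects every parameter of the simulate-gate-preprocess-score-map
#' pipeline in one validated list. The defaults reproduce the reference
#' protocol: 15 Hz flicker, 3 reference harmonics, 500 Hz EEG and 60 Hz
#' gaze sampling, 4 s epochs, 50 Hz notch plus 4-35 Hz band-pass,
#' 1.5-degree fixation ring, 12 runs of 46 stimuli, 31 channels with the
#' 11-channel occipito-parietal scoring subset, and alpha 0.05.
#'
#' @param layout An [build_layout()] layout.
#' @param montage An [default_montage()] montage.
#' @param sim A [sim_params()] object.
#' @param filter A [filter_spec()] object.
#' @param f Stimulation frequency used for scoring, Hz.
#' @param M Number of reference harmonics.
#' @param channels Scoring channel subset (labels).
#' @param n_runs Runs per participant.
#' @param n_participants Number of simulated participants.
#' @param duration_s Trial duration, seconds.
#' @param fs_eeg,fs_gaze Sampling rates, Hz.
#' @param ring_radius Fixation ring radius, degrees.
#' @param error_rate_method `"runwise"` or `"pooled"` (see [error_rate()]).
#' @param alpha Significance level.
#' @param seed Master seed; participant p is simulated with
#'   `seed + p - 1`.
#' @param contributions Compute the leave-one-out contribution maps
#'   (the most expensive stage)?
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(layout = build_layout(),
                            montage = default_montage(),
                            sim = sim_params(),
                            filter = filter_spec(),
                            f = 15, M = 3,
                            channels = attr(default_montage(), "analysis_subset"),
                            n_runs = 12, n_participants = 8,
                            duration_s = 4, fs_eeg = 500, fs_gaze = 60,
                            ring_radius = 1.5,
                            error_rate_method = "runwise",
                            alpha = 0.05, seed = 1,
                            contributions = FALSE) {
  cfg <- structure(list(
    layout = layout, montage = montage, sim = sim, filter = filter,
    f = f, M = M, channels = channels,
    n_runs = n_runs, n_participants = n_participants,
    duration_s = duration_s, fs_eeg = fs_eeg, fs_gaze = fs_gaze,
    ring_radius = ring_radius, error_rate_method = error_rate_method,
    alpha = alpha, seed = seed, contributions = contributions
  ), class = "pipeline_config")
  v <- validate_config(cfg)
  if (length(v)) stop(paste(c("invalid configuration:", v), collapse = "\n  "))
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks the structural invariants of a configuration and returns a
#' character vector of human-readable violations (empty when the
#' configuration is valid).
#'
#' @param config A `pipeline_config` (or a bare list with the same fields).
#' @return Character vector of violations; `character(0)` if ok.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(inherits(config$layout, "ssvep_layout"), "layout: not an ssvep_layout")
  ok_montage <- !inherits(try(validate_montage(config$montage), silent = TRUE),
                          "try-error")
  chk(ok_montage, "montage: invalid")
  chk(inherits(config$sim, "sim_params"), "sim: not a sim_params object")
  chk(inherits(config$filter, "filter_spec"), "filter: not a filter_spec")
  chk(config$f > 0, "f: must be positive")
  chk(config$M >= 1, "M: need at least one harmonic")
  chk(config$M * config$f < config$fs_eeg / 2,
      sprintf("M, f, fs_eeg: harmonic %d x %g Hz reaches Nyquist (%g Hz)",
              config$M, config$f, config$fs_eeg / 2))
  if (ok_montage) {
    unknown <- setdiff(config$channels, config$montage$label)
    chk(length(unknown) == 0,
        sprintf("channels: unknown label(s) %s", paste(unknown, collapse = ", ")))
  }
  chk(config$n_runs >= 1, "n_runs: must be >= 1")
  chk(config$n_participants >= 1, "n_participants: must be >= 1")
  chk(config$ring_radius > 0, "ring_radius: must be positive")
  chk(config$alpha > 0 && config$alpha < 1, "alpha: must be in (0, 1)")
  if (inherits(config$filter, "filter_spec")) {
    chk(config$fs_eeg > 2 * config$filter$band[2],
        "fs_eeg, filter: sampling rate too low for the band-pass edge")
  }
  v
}

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates `n_participants` gaze-restricted sessions, re-applies the
#' fixation-ring gate, filters the valid epochs, scores them by canonical
#' correlation, and assembles every output table: the response table,
#' per-position means, layer averages, the error-rate table, interpolated
#' response surfaces, the single-channel and contralateral-effect tables,
#' optionally the leave-one-out contribution maps, and a run manifest
#' (seed, parameters, trial-rejection counts) sufficient to reproduce the
#' run.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage boundaries and rejection counts?
#' @return An object of class `ssvep_report` (a list of tables; see
#'   Details).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  v <- validate_config(config)
  if (length(v)) stop(paste(c("invalid configuration:", v), collapse = "\n  "))
  say <- function(...) if (verbose) message(sprintf(...))

  sessions <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    sim <- config$sim
    if (!is.null(config$seed)) sim$seed <- config$seed + p - 1
    say("[simulate] participant S%d (seed %s)", p,
        if (is.null(sim$seed)) "<inherited>" else sim$seed)
    s <- simulate_session(sim, config$layout, config$montage,
                          n_runs = config$n_runs,
                          duration_s = config$duration_s,
                          fs_eeg = config$fs_eeg, fs_gaze = config$fs_gaze,
                          ring_radius = config$ring_radius,
                          participant = sprintf("S%d", p))
    s <- gate_session(s, config$ring_radius)
    say("[gate] %s: %d attempts, %d rejected", s$participant,
        length(s$trials), sum(!vapply(s$trials, `[[`, logical(1), "valid")))
    sessions[[p]] <- preprocess_session(s, config$filter)
  }

  say("[score] CCA on %s", paste(config$channels, collapse = ", "))
  rt <- response_table(sessions, f = config$f, M = config$M,
                       channels = config$channels)
  pm <- position_means(rt)
  say("[map] layer averages, error rates, surfaces")
  layers <- layer_average(rt, config$layout)
  ert <- error_rate_table(rt, config$layout, method = config$error_rate_method)
  surfaces <- lapply(split(pm, pm$participant), surface_grid,
                     layout = config$layout)

  say("[topography] single-channel responses and contralateral scores")
  sc <- single_channel_table(sessions, f = config$f, M = config$M)
  ct <- contralateral_table(sc, config$layout,
                            pairs = attr(config$montage, "pairs"),
                            alpha = config$alpha)
  cmaps <- NULL
  if (isTRUE(config$contributions)) {
    say("[topography] leave-one-out contribution maps")
    cmaps <- lapply(sessions, contribution_map,
                    f = config$f, M = config$M, montage = config$montage)
    names(cmaps) <- vapply(sessions, `[[`, character(1), "participant")
  }

  attempts <- do.call(rbind, lapply(sessions, function(s) {
    tt <- session_trial_table(s)
    data.frame(participant = s$participant,
               attempts = nrow(tt), valid = sum(tt$valid),
               rejected = sum(!tt$valid))
  }))
  structure(list(
    response_table = rt,
    position_means = pm,
    layer_means = layers,
    error_rate_table = ert,
    surfaces = surfaces,
    single_channel = sc,
    contralateral = ct,
    contribution_maps = cmaps,
    manifest = list(
      seed = config$seed,
      n_participants = config$n_participants,
      n_runs = config$n_runs,
      trial_counts = attempts,
      r_version = as.character(getRversion()),
      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "ssvep_report")
}

#' @export
print.ssvep_report <- function(x, ...) {
  tc <- x$manifest$trial_counts
  cat(sprintf(
    "SSVEP pipeline report: %d participant(s), %d run(s); %d valid / %d rejected trials\n",
    x$manifest$n_participants, x$manifest$n_runs,
    sum(tc$valid), sum(tc$rejected)))
  cat("Layer means:\n")
  print(round(x$layer_means, 4))
  invisible(x)
}

#' Write a report's tables to a directory
#'
#' Serializes every table of an [run_pipeline()] report as delimited text:
#' the response table, position means, layer means, error-rate table,
#' contralateral table, per-participant surface grids (dense matrices with
#' a coordinate header), contribution maps, and the manifest.
#'
#' @param report An `ssvep_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ssvep_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(report$response_table, "response_table.csv")
  wr(report$position_means, "position_means.csv")
  wr(data.frame(layer = names(report$layer_means),
                mean_r = as.numeric(report$layer_means)), "layer_means.csv")
  wr(report$error_rate_table, "error_rate_table.csv")
  wr(report$single_channel, "single_channel.csv")
  wr(report$contralateral, "contralateral.csv")
  for (p in names(report$surfaces)) {
    g <- report$surfaces[[p]]
    path <- file.path(dir, sprintf("surface_%s.tsv", p))
    con <- file(path, "w")
    writeLines(c(paste0("# x=", paste(sprintf("%.6g", g$x), collapse = ",")),
                 paste0("# y=", paste(sprintf("%.6g", g$y), collapse = ","))),
               con)
    utils::write.table(g$z, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    close(con)
  }
  if (!is.null(report$contribution_maps)) {
    for (p in names(report$contribution_maps)) {
      m <- report$contribution_maps[[p]]
      utils::write.csv(cbind(channel = rownames(m), as.data.frame(unclass(m))),
                       file.path(dir, sprintf("contributions_%s.csv", p)),
                       row.names = FALSE)
    }
  }
  tc <- report$manifest$trial_counts
  wr(tc, "trial_counts.csv")
  writeLines(c(
    sprintf("seed=%s", report$manifest$seed),
    sprintf("n_participants=%d", report$manifest$n_participants),
    sprintf("n_runs=%d", report$manifest$n_runs),
    sprintf("r_version=%s", report$manifest$r_version),
    sprintf("timestamp=%s", report$manifest$timestamp)),
    file.path(dir, "manifest.txt"))
  invisible(dir)
}
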