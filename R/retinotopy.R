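#' SSVEP response table for one or more sessions
#'
#' Scores every valid trial of a session by canonical correlation against
#' the harmonic reference, using the occipito-parietal analysis subset of
#' channels (the package's "SSVEP response"). Per-trial scoring with
#' across-run averaging downstream is the default analysis path.
#'
#' @param session An `ssvep_session`, or a list of them.
#' @param f Stimulation frequency, Hz.
#' @param M Number of reference harmonics.
#' @param channels Channel labels to score over; defaults to the
#'   11-channel occipito-parietal subset of [default_montage()].
#' @return A data frame of class `response_table` with columns
#'   `participant`, `run`, `stimulus`, `r` (one row per valid trial).
#' @export
response_table <- function(session, f = 15, M = 3, channels = NULL) {
  if (inherits(session, "ssvep_session")) session <- list(session)
  if (is.null(channels)) channels <- attr(default_montage(), "analysis_subset")
  out <- lapply(session, function(s) {
    stopifnot(inherits(s, "ssvep_session"))
    missing <- setdiff(channels, s$channels)
    if (length(missing)) {
      stop(sprintf("session %s lacks channel(s): %s",
                   s$participant, paste(missing, collapse = ", ")))
    }
    valid <- Filter(function(tr) tr$valid, s$trials)
    if (!length(valid)) return(NULL)
    N <- ncol(valid[[1]]$eeg)
    Y <- build_reference(f, M, s$fs_eeg, N)
    data.frame(
      participant = s$participant,
      run = vapply(valid, `[[`, numeric(1), "run"),
      stimulus = vapply(valid, `[[`, numeric(1), "stimulus"),
      r = vapply(valid, function(tr) {
        cca_coefficient(tr$eeg[channels, , drop = FALSE], Y)$R
      }, numeric(1))
    )
  })
  out <- do.call(rbind, out)
  class(out) <- c("response_table", "data.frame")
  out
}

#' Mean response of one stimulus position
#'
#' Arithmetic mean of the valid-trial responses of one stimulus for one
#' participant; `NA` with a warning when the stimulus has no valid trial.
#'
#' @param table A [response_table()].
#' @param participant Participant id.
#' @param stimulus Stimulus index.
#' @return Numeric scalar (possibly `NA`).
#' @export
position_mean_response <- function(table, participant, stimulus) {
  v <- table$r[table$participant == participant & table$stimulus == stimulus]
  if (!length(v)) {
    warning(sprintf("no valid trials for participant %s stimulus %d",
                    participant, stimulus))
    return(NA_real_)
  }
  mean(v)
}

#' Per-position mean responses
#'
#' @param table A [response_table()].
#' @return Data frame `participant`, `stimulus`, `mean_r`.
#' @export
position_means <- function(table) {
  agg <- stats::aggregate(r ~ participant + stimulus, data = table, FUN = mean)
  names(agg)[names(agg) == "r"] <- "mean_r"
  agg[order(agg$participant, agg$stimulus), , drop = FALSE]
}

#' Average response per layer
#'
#' Mean response over the stimuli of each layer within participant, then
#' averaged over participants.
#'
#' @param table A [response_table()].
#' @param layout An `ssvep_layout`.
#' @return Named numeric vector, one mean per layer (names `"1"`..).
#' @export
layer_average <- function(table, layout) {
  pm <- position_means(table)
  pm$layer <- layout$layer[pm$stimulus]
  per_part <- stats::aggregate(mean_r ~ participant + layer, data = pm, FUN = mean)
  agg <- stats::aggregate(mean_r ~ layer, data = per_part, FUN = mean)
  out <- agg$mean_r
  names(out) <- agg$layer
  out
}

# stimuli whose eccentricity matches visual angle d (a single layer)
.layer_stimuli_at <- function(layout, d) {
  ecc <- sqrt(rowSums(layout$positions^2))
  which(abs(ecc - d) < 1e-6)
}

#' Central-versus-peripheral error rate
#'
#' The competitive-effect statistic: how often peripheral stimuli at visual
#' angle `d` out-respond the central stimulus. Under the default `"runwise"`
#' definition an error event occurs in a run when the maximum response over
#' the layer-`d` stimuli of that run exceeds that run's central-stimulus
#' response; the rate is the percentage of such runs among runs with
#' complete data at `d` (so 12 usable runs yield multiples of 1/12, and a
#' dropped run yields multiples of 1/11). The `"pooled"` variant counts
#' every (run, stimulus) comparison separately.
#'
#' @param table A [response_table()].
#' @param layout An `ssvep_layout`.
#' @param participant Participant id.
#' @param d Visual angle in degrees (one of the ring eccentricities).
#' @param method `"runwise"` (default) or `"pooled"`.
#' @return List with `rate` (percent) and `n_runs_used`.
#' @export
error_rate <- function(table, layout, participant, d,
                       method = c("runwise", "pooled")) {
  method <- match.arg(method)
  tb <- table[table$participant == participant, , drop = FALSE]
  central_idx <- which(layout$layer == 1L)
  stopifnot(length(central_idx) == 1)
  peri_idx <- .layer_stimuli_at(layout, d)
  if (!length(peri_idx)) stop(sprintf("no stimuli at visual angle %g", d))
  central <- tb[tb$stimulus == central_idx, c("run", "r")]
  if (!nrow(central)) stop("central stimulus has no valid trials")
  peri <- tb[tb$stimulus %in% peri_idx, c("run", "stimulus", "r")]
  if (method == "runwise") {
    errors <- 0L; usable <- 0L
    for (run in central$run) {
      pv <- peri$r[peri$run == run]
      if (length(pv) < length(peri_idx)) next  # incomplete run at this angle
      usable <- usable + 1L
      if (max(pv) > central$r[central$run == run]) errors <- errors + 1L
    }
    if (usable == 0L) stop("no usable runs at this angle")
    list(rate = 100 * errors / usable, n_runs_used = usable)
  } else {
    cv <- stats::setNames(central$r, central$run)
    keep <- peri$run %in% central$run
    peri <- peri[keep, , drop = FALSE]
    if (!nrow(peri)) stop("no usable comparisons at this angle")
    list(rate = 100 * mean(peri$r > cv[as.character(peri$run)]),
         n_runs_used = nrow(central))
  }
}

#' Average error rates across participants
#'
#' @param rates Numeric matrix or data frame, participants x angles, of
#'   error rates in percent.
#' @return Named numeric vector, the per-angle arithmetic mean rounded to
#'   2 decimals.
#' @export
average_error_rates <- function(rates) {
  m <- as.matrix(rates)
  round(colMeans(m), 2)
}

#' Two-sample t-test of central versus peripheral responses
#'
#' Welch two-sample, two-sided t-test comparing the per-run responses of
#' the central stimulus against the per-run responses of the layer-`d`
#' stimuli (pooled over the stimuli of that layer). When both groups have
#' zero variance the p-value follows the degenerate convention: 1 if the
#' means are equal, 0 otherwise (with a warning).
#'
#' @inheritParams error_rate
#' @return Two-sided p-value.
#' @export
central_peripheral_ttest <- function(table, layout, participant, d) {
  tb <- table[table$participant == participant, , drop = FALSE]
  central_idx <- which(layout$layer == 1L)
  peri_idx <- .layer_stimuli_at(layout, d)
  g1 <- tb$r[tb$stimulus == central_idx]
  g2 <- tb$r[tb$stimulus %in% peri_idx]
  if (length(g1) < 2 || length(g2) < 2) stop("need at least 2 values per group")
  if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
    warning("zero variance in both groups; degenerate p-value convention")
    return(if (isTRUE(all.equal(mean(g1), mean(g2)))) 1 else 0)
  }
  stats::t.test(g1, g2, var.equal = FALSE)$p.value
}

#' Error-rate table across participants and visual angles
#'
#' Builds the participants x angles competitive-effect table: per cell the
#' error rate (percent) and the central-versus-peripheral t-test p-value,
#' plus an `AVE` row of across-participant mean rates.
#'
#' @param table A [response_table()].
#' @param layout An `ssvep_layout`.
#' @param angles Visual angles to tabulate, degrees.
#' @param method Error-rate variant, see [error_rate()].
#' @return Data frame with columns `participant`, `angle`, `rate`,
#'   `p_value`, `n_runs_used` (the `AVE` rows carry `NA` p-values).
#' @export
error_rate_table <- function(table, layout, angles = c(2, 4, 6, 8, 10),
                             method = "runwise") {
  participants <- unique(table$participant)
  rows <- list()
  for (p in participants) {
    for (d in angles) {
      er <- error_rate(table, layout, p, d, method)
      pv <- tryCatch(central_peripheral_ttest(table, layout, p, d),
                     error = function(e) NA_real_)  # e.g. a single run
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, angle = d, rate = er$rate,
        p_value = pv, n_runs_used = er$n_runs_used)
    }
  }
  out <- do.call(rbind, rows)
  ave <- do.call(rbind, lapply(angles, function(d) {
    data.frame(participant = "AVE", angle = d,
               rate = round(mean(out$rate[out$angle == d]), 2),
               p_value = NA_real_, n_runs_used = NA_integer_)
  }))
  rbind(out, ave)
}

#' Interpolated response surface over the visual field
#'
#' Piecewise-linear interpolation of the per-position mean responses over
#' the triangulated stimulus positions: the surface passes exactly through
#' the measured values, and grid nodes outside the convex hull of the
#' stimulus positions are `NA`.
#'
#' @param values Named numeric vector of per-stimulus mean responses
#'   (names are stimulus indices), or a [position_means()] data frame for
#'   one participant.
#' @param layout An `ssvep_layout`.
#' @param grid_resolution Number of grid nodes per axis.
#' @return List with vectors `x`, `y` (degrees) and matrix `z`
#'   (length(x) x length(y)).
#' @export
surface_grid <- function(values, layout, grid_resolution = 101) {
  if (is.data.frame(values)) {
    stopifnot(length(unique(values$participant)) == 1)
    values <- stats::setNames(values$mean_r, values$stimulus)
  }
  idx <- as.integer(names(values))
  keep <- !is.na(values)
  idx <- idx[keep]; values <- values[keep]
  if (length(idx) < 3) stop("need at least 3 positions")
  x <- layout$positions[idx, "x"]
  y <- layout$positions[idx, "y"]
  # concentric layouts are co-circular, which makes the Delaunay step retry
  # with internal jitter; that warning is expected and harmless (node values
  # are preserved to ~1e-6)
  res <- withCallingHandlers(
    tryCatch(
      interp::interp(x, y, as.numeric(values),
                     nx = grid_resolution, ny = grid_resolution,
                     method = "linear"),
      error = function(e) stop("degenerate layout: ", conditionMessage(e))),
    warning = function(w) {
      if (grepl("shull", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  list(x = res$x, y = res$y, z = res$z)
}
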