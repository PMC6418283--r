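# covariance triple of a centered epoch against a reference
.cov_triple <- function(X, Y) {
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  list(Cxx = tcrossprod(Xc) / n,
       Cxy = tcrossprod(Xc, Yc) / n,
       Cyy = tcrossprod(Yc) / n)
}

#' Leave-one-out single-channel contribution
#'
#' The contribution of channel i to SSVEP detection is the normalized drop
#' of the all-channel canonical correlation when the channel is removed:
#' \deqn{r_i = (R_{all} - R_{-i}) / R_{all},}
#' where \eqn{R_{all}} uses all C channels and \eqn{R_{-i}} omits channel
#' i. (The printed definition in the source literature sums CCA outcomes
#' over channel index sets; read literally it cancels to this same
#' "with and without the channel" difference, which is what is
#' implemented.) By the nesting property of canonical correlation
#' \eqn{R_{-i} \le R_{all}}, so \eqn{r_i \le 1}, with equality only if
#' removing the channel drives R to 0; a duplicated channel contributes 0.
#'
#' @param epochs A channels x samples matrix, or a list of them (the
#'   contribution is averaged over epochs).
#' @param Y Reference matrix from [build_reference()].
#' @param channel Channel label or index to leave out.
#' @return Numeric scalar; `NA` with a warning when `R_all` is 0.
#' @export
channel_contribution <- function(epochs, Y, channel) {
  if (is.matrix(epochs)) epochs <- list(epochs)
  vals <- vapply(epochs, function(X) {
    if (is.character(channel)) {
      ch <- match(channel, rownames(X))
      if (is.na(ch)) stop("unknown channel label")
    } else ch <- channel
    stopifnot(nrow(X) >= 2)
    cv <- .cov_triple(X, unclass(Y))
    r_all <- .cca_from_cov(cv$Cxx, cv$Cxy, cv$Cyy)$R
    if (r_all == 0) return(NA_real_)
    r_wo <- .cca_from_cov(cv$Cxx[-ch, -ch, drop = FALSE],
                          cv$Cxy[-ch, , drop = FALSE], cv$Cyy)$R
    (r_all - r_wo) / r_all
  }, numeric(1))
  if (anyNA(vals)) warning("contribution undefined for epoch(s) with R_all = 0")
  mean(vals, na.rm = TRUE)
}

#' Channel-contribution map of a session
#'
#' Leave-one-out contributions of every channel for every stimulus,
#' averaged over valid runs. Each trial's covariance structure is computed
#' once and the leave-one-out coefficients are obtained from its
#' submatrices.
#'
#' @param session An `ssvep_session`.
#' @param f Stimulation frequency, Hz.
#' @param M Number of reference harmonics.
#' @param montage An `eeg_montage` supplying plotting coordinates.
#' @return A channels x stimuli numeric matrix of class `contribution_map`
#'   with the montage stored as attribute `montage`.
#' @export
contribution_map <- function(session, f = 15, M = 3,
                             montage = default_montage()) {
  stopifnot(inherits(session, "ssvep_session"))
  valid <- Filter(function(tr) tr$valid, session$trials)
  if (!length(valid)) stop("session has no valid trials")
  N <- ncol(valid[[1]]$eeg)
  Y <- unclass(build_reference(f, M, session$fs_eeg, N))
  C <- length(session$channels)
  stimuli <- sort(unique(vapply(valid, `[[`, numeric(1), "stimulus")))
  acc <- matrix(0, C, length(stimuli),
                dimnames = list(session$channels, stimuli))
  cnt <- integer(length(stimuli))
  for (tr in valid) {
    cv <- .cov_triple(tr$eeg, Y)
    r_all <- .cca_from_cov(cv$Cxx, cv$Cxy, cv$Cyy)$R
    if (r_all == 0) next
    ri <- vapply(seq_len(C), function(ch) {
      r_wo <- .cca_from_cov(cv$Cxx[-ch, -ch, drop = FALSE],
                            cv$Cxy[-ch, , drop = FALSE], cv$Cyy)$R
      (r_all - r_wo) / r_all
    }, numeric(1))
    j <- match(tr$stimulus, stimuli)
    acc[, j] <- acc[, j] + ri
    cnt[j] <- cnt[j] + 1L
  }
  if (any(cnt == 0)) warning("some stimuli had no usable trials")
  map <- sweep(acc, 2, pmax(cnt, 1L), "/")
  map[, cnt == 0] <- NA_real_
  structure(map, montage = montage,
            class = c("contribution_map", "matrix", "array"))
}

#' Per-stimulus single-channel response table
#'
#' Single-channel canonical correlations (channel versus harmonic
#' reference) averaged over the valid runs of each stimulus — the `r`
#' values entering the contralateral-effect score.
#'
#' @param session An `ssvep_session` or list of sessions.
#' @param channels Channel labels to score (default: the union of the four
#'   mirror pairs of [default_montage()]).
#' @param f,M Reference frequency and harmonic count.
#' @return Data frame `participant`, `stimulus`, `channel`, `r`.
#' @export
single_channel_table <- function(session, channels = NULL, f = 15, M = 3) {
  if (inherits(session, "ssvep_session")) session <- list(session)
  if (is.null(channels)) {
    channels <- unlist(attr(default_montage(), "pairs"))
  }
  rows <- lapply(session, function(s) {
    valid <- Filter(function(tr) tr$valid, s$trials)
    if (!length(valid)) return(NULL)
    N <- ncol(valid[[1]]$eeg)
    Y <- build_reference(f, M, s$fs_eeg, N)
    per_trial <- do.call(rbind, lapply(valid, function(tr) {
      data.frame(participant = s$participant, stimulus = tr$stimulus,
                 channel = channels,
                 r = vapply(channels, function(ch) {
                   single_channel_response(tr$eeg, ch, Y)
                 }, numeric(1)))
    }))
    agg <- stats::aggregate(r ~ participant + stimulus + channel,
                            data = per_trial, FUN = mean)
    agg
  })
  do.call(rbind, rows)
}

#' Contralateral-effect score of a channel pair
#'
#' For stimuli on side `s` of the visual field within visual angle `d`,
#' the score of mirror pair `p = (p_left, p_right)` is
#' \deqn{E_{s,d,p} = \mathrm{avg}_k(r_{s,k,p_{left}}) / r_{0,0,p_{left}}
#'                 - \mathrm{avg}_k(r_{s,k,p_{right}}) / r_{0,0,p_{right}},}
#' the mean single-channel response over the K stimuli of that side and
#' angle, normalized per channel by the central-stimulus response (which
#' absorbs hemisphere differences unrelated to the stimulus). Positive E
#' means the left channel dominates — the expected sign for right-hemifield
#' stimuli under a contralateral organization. "Within angle d" is
#' cumulative (all stimuli with eccentricity up to `d`); set
#' `within = "layer"` for the single-ring variant.
#'
#' @param r_single A [single_channel_table()] data frame (one participant
#'   or several; values are pooled).
#' @param layout An `ssvep_layout`.
#' @param s Stimulus side, `"left"` or `"right"`.
#' @param d Visual angle, degrees.
#' @param pair Character vector `c(left_label, right_label)`.
#' @param within `"cumulative"` (default) or `"layer"`.
#' @return Numeric scalar E (`NA` when no stimulus qualifies).
#' @export
contralateral_score <- function(r_single, layout, s, d, pair,
                                within = c("cumulative", "layer")) {
  within <- match.arg(within)
  s <- match.arg(s, c("left", "right"))
  stopifnot(length(pair) == 2)
  central_idx <- which(layout$layer == 1L)
  idx <- stimuli_within(layout, d, side = s)
  if (within == "layer") {
    idx <- intersect(idx, .layer_stimuli_at(layout, d))
  }
  if (!length(idx)) return(NA_real_)
  term <- function(ch) {
    ref <- r_single$r[r_single$stimulus == central_idx & r_single$channel == ch]
    if (!length(ref) || any(ref <= 0)) {
      stop(sprintf("central reference response for %s missing or non-positive", ch))
    }
    vals <- r_single[r_single$stimulus %in% idx & r_single$channel == ch, ]
    # normalize within participant by that participant's own reference
    refs <- stats::setNames(ref, r_single$participant[
      r_single$stimulus == central_idx & r_single$channel == ch])
    mean(vals$r / refs[as.character(vals$participant)])
  }
  term(pair[1]) - term(pair[2])
}

#' Kruskal-Wallis comparison of a mirror pair
#'
#' Rank-based Kruskal-Wallis test between the normalized per-stimulus
#' responses of the pair's left and right channels (used instead of a
#' t-test because the normalized scores are not normally distributed).
#' All-tied samples return H = 0, p = 1.
#'
#' @param left_values,right_values Numeric vectors.
#' @param alpha Significance level for the flag.
#' @return List with `H`, `p` and logical `significant`.
#' @export
kw_significance <- function(left_values, right_values, alpha = 0.05) {
  stopifnot(length(left_values) >= 2, length(right_values) >= 2)
  x <- c(left_values, right_values)
  if (length(unique(x)) == 1L) {
    return(list(H = 0, p = 1, significant = FALSE))
  }
  kt <- stats::kruskal.test(list(left_values, right_values))
  list(H = unname(kt$statistic), p = kt$p.value,
       significant = kt$p.value < alpha)
}

#' Contralateral-effect score table
#'
#' The full pair x angle x side table of contralateral scores with
#' Kruskal-Wallis significance flags, pooling normalized per-stimulus
#' responses over participants.
#'
#' @param r_single A [single_channel_table()] data frame.
#' @param layout An `ssvep_layout`.
#' @param pairs List of `c(left, right)` label pairs; defaults to the four
#'   occipito-parietal mirror pairs.
#' @param angles Visual angles, degrees.
#' @param alpha KW significance level.
#' @param within See [contralateral_score()].
#' @return Data frame `pair`, `angle`, `side`, `score`, `H`, `p`,
#'   `significant`.
#' @export
contralateral_table <- function(r_single, layout, pairs = NULL,
                                angles = c(2, 4, 6, 8, 10), alpha = 0.05,
                                within = "cumulative") {
  if (is.null(pairs)) pairs <- attr(default_montage(), "pairs")
  central_idx <- which(layout$layer == 1L)
  rows <- list()
  for (pr in pairs) {
    for (d in angles) {
      for (s in c("left", "right")) {
        idx <- stimuli_within(layout, d, side = s)
        if (within == "layer") idx <- intersect(idx, .layer_stimuli_at(layout, d))
        norm_vals <- function(ch) {
          refs <- r_single[r_single$stimulus == central_idx &
                             r_single$channel == ch, ]
          refs_v <- stats::setNames(refs$r, refs$participant)
          vals <- r_single[r_single$stimulus %in% idx &
                             r_single$channel == ch, ]
          vals$r / refs_v[as.character(vals$participant)]
        }
        lv <- norm_vals(pr[1]); rv <- norm_vals(pr[2])
        kw <- if (length(lv) >= 2 && length(rv) >= 2) {
          kw_significance(lv, rv, alpha)
        } else {
          # too few pooled stimuli for a rank test (e.g. one participant at 2 deg)
          list(H = NA_real_, p = NA_real_, significant = NA)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          pair = paste(pr, collapse = "-"), angle = d, side = s,
          score = contralateral_score(r_single, layout, s, d, pr, within),
          H = kw$H, p = kw$p, significant = kw$significant)
      }
    }
  }
  do.call(rbind, rows)
}
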