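#' EEG recording container
#'
#' A light container for a continuous or epoched multichannel EEG segment:
#' a channels x samples matrix plus sampling rate and channel labels.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate, Hz.
#' @param labels Channel labels; defaults to the matrix row names.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = rownames(data)) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  stopifnot(length(labels) == nrow(data), fs > 0)
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples at %g Hz (%.3g s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Read and write EEG as a delimited channel matrix
#'
#' The interchange format is plain text: an optional comment header
#' `# fs=<Hz>`, then one row per channel whose first field is the channel
#' label followed by the samples, tab-separated.
#'
#' @param path File path.
#' @param fs Sampling rate; taken from the file header when present.
#' @param expected_labels Optional character vector; if given, the file must
#'   contain exactly these channels (an error names any missing label) and
#'   channels are returned in this order.
#' @param expected_fs Optional; a mismatch with the file's rate warns.
#' @return `read_eeg()` returns an [eeg_recording()].
#' @export
read_eeg <- function(path, fs = NULL, expected_labels = NULL,
                     expected_fs = NULL) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("fs=([0-9.eE+-]+)", lines[1]))[[1]]
    if (length(m) == 2) fs <- as.numeric(m[2])
    lines <- lines[-1]
  }
  if (is.null(fs)) stop("sampling rate not in file header; pass fs=")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  labels <- vapply(parts, `[`, character(1), 1)
  data <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(data) <- labels
  if (!is.null(expected_labels)) {
    missing <- setdiff(expected_labels, labels)
    if (length(missing)) {
      stop(sprintf("missing channel(s): %s", paste(missing, collapse = ", ")))
    }
    extra <- setdiff(labels, expected_labels)
    if (length(extra)) {
      stop(sprintf("unknown channel label(s): %s", paste(extra, collapse = ", ")))
    }
    data <- data[expected_labels, , drop = FALSE]
    labels <- expected_labels
  }
  if (!is.null(expected_fs) && !isTRUE(all.equal(fs, expected_fs))) {
    warning(sprintf("file sampling rate %g Hz differs from expected %g Hz",
                    fs, expected_fs))
  }
  eeg_recording(data, fs, labels)
}

#' @rdname read_eeg
#' @param recording An [eeg_recording()].
#' @param digits Significant digits written per sample.
#' @export
write_eeg <- function(recording, path, digits = 7) {
  stopifnot(inherits(recording, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", recording$fs), con)
  fmt <- paste0("%.", digits, "g")
  for (i in seq_len(nrow(recording$data))) {
    writeLines(paste(c(recording$labels[i],
                       sprintf(fmt, recording$data[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read and write gaze traces
#'
#' Gaze traces are stored as tab-separated text with columns
#' `t_s`, `x_deg`, `y_deg`.
#'
#' @param gaze Matrix with columns `x_deg`, `y_deg`.
#' @param fs Gaze sampling rate, Hz (first sample at t = 1/fs).
#' @param path File path.
#' @return `read_gaze()` returns a matrix with columns `x_deg`, `y_deg`
#'   and attribute `fs`.
#' @export
write_gaze <- function(gaze, fs, path) {
  df <- data.frame(t_s = seq_len(nrow(gaze)) / fs,
                   x_deg = gaze[, "x_deg"], y_deg = gaze[, "y_deg"])
  utils::write.table(format(df, digits = 9, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("t_s", "x_deg", "y_deg") %in% names(df)))
  g <- cbind(x_deg = df$x_deg, y_deg = df$y_deg)
  if (nrow(df) >= 2) attr(g, "fs") <- 1 / (df$t_s[2] - df$t_s[1])
  g
}

#' Serialize a session to a directory of plain-text files
#'
#' Writes one EEG matrix and one gaze trace per trial attempt plus a
#' `trials.csv` metadata sidecar (run, stimulus, attempt, valid, file
#' names) and a `session.csv` header (participant, sampling rates).
#'
#' @param session An `ssvep_session`.
#' @param dir Output directory (created if needed).
#' @return `read_session()` returns an `ssvep_session`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ssvep_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- session_trial_table(session)
  meta$eeg_file <- sprintf("trial%03d_eeg.tsv", seq_len(nrow(meta)))
  meta$gaze_file <- sprintf("trial%03d_gaze.tsv", seq_len(nrow(meta)))
  utils::write.csv(
    data.frame(participant = session$participant, fs_eeg = session$fs_eeg,
               fs_gaze = session$fs_gaze, duration_s = session$duration_s),
    file.path(dir, "session.csv"), row.names = FALSE)
  utils::write.csv(meta, file.path(dir, "trials.csv"), row.names = FALSE)
  for (i in seq_along(session$trials)) {
    tr <- session$trials[[i]]
    write_eeg(eeg_recording(tr$eeg, session$fs_eeg, session$channels),
              file.path(dir, meta$eeg_file[i]))
    write_gaze(tr$gaze, session$fs_gaze, file.path(dir, meta$gaze_file[i]))
  }
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  hdr <- utils::read.csv(file.path(dir, "session.csv"))
  meta <- utils::read.csv(file.path(dir, "trials.csv"))
  trials <- vector("list", nrow(meta))
  channels <- NULL
  for (i in seq_len(nrow(meta))) {
    rec <- read_eeg(file.path(dir, meta$eeg_file[i]))
    if (is.null(channels)) channels <- rec$labels
    trials[[i]] <- list(
      run = meta$run[i], stimulus = meta$stimulus[i],
      attempt = meta$attempt[i],
      eeg = rec$data,
      gaze = read_gaze(file.path(dir, meta$gaze_file[i])),
      valid = as.logical(meta$valid[i]))
  }
  structure(list(
    participant = as.character(hdr$participant[1]),
    fs_eeg = hdr$fs_eeg[1], fs_gaze = hdr$fs_gaze[1],
    duration_s = hdr$duration_s[1],
    channels = channels, trials = trials
  ), class = "ssvep_session")
}
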