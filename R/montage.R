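#' Default 31-channel EEG montage
#'
#' A 31-channel arrangement following the extended international 10-20
#' system, with approximate 2-D scalp coordinates for topographic display
#' (head radius 1, x positive toward the right ear, y positive toward the
#' nose). The montage carries a hemisphere tag per channel
#' (`"L"`, `"R"`, `"M"` for midline), the four mirror-symmetric
#' occipito-parietal channel pairs used for contralateral-effect scoring
#' (O1-O2, PO3-PO4, P3-P4, P7-P8), and the 11-channel occipito-parietal
#' subset over which SSVEP responses are scored
#' (P7, P3, Pz, P4, P8, PO3, POz, PO4, O1, Oz, O2).
#'
#' Coordinates are a synthetic planar projection chosen to be exactly
#' mirror-symmetric between hemispheres; they feed the simulator's scalp
#' weighting and plotting only, not any statistic.
#'
#' @return An object of class `eeg_montage`: a data frame with columns
#'   `label`, `x`, `y`, `hemisphere`, plus attributes `pairs` (list of
#'   c(left, right) label pairs) and `analysis_subset` (character vector).
#' @examples
#' m <- default_montage()
#' nrow(m)  # 31
#' @export
default_montage <- function() {
  # (label, radius, angle in degrees clockwise from the nose; negative = left)
  spec <- list(
    c("Fp1", 1, -18),  c("Fp2", 1, 18),
    c("F7", 1, -54),   c("F3", 0.56, -39), c("Fz", 0.5, 0),
    c("F4", 0.56, 39), c("F8", 1, 54),
    c("FC5", 0.78, -69), c("FC1", 0.33, -45),
    c("FC2", 0.33, 45),  c("FC6", 0.78, 69),
    c("T7", 1, -90),  c("C3", 0.5, -90), c("Cz", 0, 0),
    c("C4", 0.5, 90), c("T8", 1, 90),
    c("CP5", 0.78, -111), c("CP1", 0.33, -135),
    c("CP2", 0.33, 135),  c("CP6", 0.78, 111),
    c("P7", 1, -126), c("P3", 0.56, -141), c("Pz", 0.5, 180),
    c("P4", 0.56, 141), c("P8", 1, 126),
    c("PO3", 0.81, -157), c("POz", 0.75, 180), c("PO4", 0.81, 157),
    c("O1", 1, -162), c("Oz", 1, 180), c("O2", 1, 162)
  )
  label <- vapply(spec, `[`, character(1), 1)
  r <- as.numeric(vapply(spec, `[`, character(1), 2))
  ang <- as.numeric(vapply(spec, `[`, character(1), 3)) * pi / 180
  df <- data.frame(
    label = label,
    x = r * sin(ang),
    y = r * cos(ang),
    hemisphere = ifelse(abs(sin(ang)) < 1e-12 | r == 0, "M",
                        ifelse(sin(ang) < 0, "L", "R")),
    stringsAsFactors = FALSE
  )
  attr(df, "pairs") <- list(
    c("O1", "O2"), c("PO3", "PO4"), c("P3", "P4"), c("P7", "P8"))
  attr(df, "analysis_subset") <- c("P7", "P3", "Pz", "P4", "P8",
                                   "PO3", "POz", "PO4", "O1", "Oz", "O2")
  class(df) <- c("eeg_montage", "data.frame")
  validate_montage(df)
  df
}

#' Validate a montage
#'
#' Checks the structural invariants the analysis relies on: 31 channels with
#' unique labels, mirror pairs are left/right labels present in the montage,
#' and the 11-channel analysis subset is fully present.
#'
#' @param montage An `eeg_montage`.
#' @return The montage, invisibly; stops on violation.
#' @export
validate_montage <- function(montage) {
  stopifnot(is.data.frame(montage),
            all(c("label", "x", "y", "hemisphere") %in% names(montage)))
  if (nrow(montage) != 31L) stop("montage must have 31 channels")
  if (anyDuplicated(montage$label)) stop("duplicate channel labels")
  pairs <- attr(montage, "pairs")
  for (p in pairs) {
    if (!all(p %in% montage$label)) {
      stop(sprintf("pair %s-%s not present in montage", p[1], p[2]))
    }
    h <- montage$hemisphere[match(p, montage$label)]
    if (!identical(h, c("L", "R"))) {
      stop(sprintf("pair %s-%s is not a left-right mirror pair", p[1], p[2]))
    }
  }
  subset <- attr(montage, "analysis_subset")
  if (length(subset) != 11L || !all(subset %in% montage$label)) {
    stop("analysis subset must list 11 channels present in the montage")
  }
  invisible(montage)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("EEG montage: %d channels (extended 10-20), %d mirror pairs\n",
              nrow(x), length(attr(x, "pairs"))))
  NextMethod()
}
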