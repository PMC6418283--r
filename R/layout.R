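#' Concentric flicker stimulus layout
#'
#' Builds the concentric multi-ring arrangement of flicker stimuli used for
#' retinotopic SSVEP mapping: one central flicker at fixation plus a set of
#' rings ("layers") at equally spaced eccentricities. All coordinates are
#' degrees of visual angle with fixation at the origin, x positive rightward
#' and y positive upward.
#'
#' The default geometry places 46 stimuli in six layers: the central flicker
#' (layer 1) and rings of 3, 6, 9, 12 and 15 stimuli at eccentricities of 2,
#' 4, 6, 8 and 10 degrees, so that the arc length between neighbours on every
#' ring is a uniform ~4.19 degrees. With a 3-degree flicker diameter the
#' stimulated field extends to a half-angle of 11.5 degrees.
#'
#' Because stimuli are presented one at a time, flickers on *different* rings
#' may sit closer than one diameter; overlap is only forbidden between
#' neighbours within the same ring (they would occupy the same annulus).
#'
#' @param layer_spacing Radial distance between adjacent layers, degrees.
#' @param flicker_diameter Diameter of each flicker disc, degrees.
#' @param ring_counts Integer vector, number of stimuli on each ring
#'   (layers 2..length+1, innermost first).
#' @param angular_offsets Polar-angle offset of the first stimulus on each
#'   ring, degrees counter-clockwise from the positive x axis. By default
#'   each ring's offset starts at half its arc step and is halved until no
#'   stimulus of the ring falls on the horizontal or vertical meridian, so
#'   hemifield and vertical-field labels are total over the rings (for the
#'   default ring counts this yields offsets of 15, 15, 5, 15 and 3
#'   degrees).
#'
#' @return An object of class `ssvep_layout`: a list with `positions`
#'   (n x 2 matrix, degrees), `layer` (integer vector), `flicker_diameter`,
#'   `layer_spacing`, `ring_counts`, `radii`, and `field_half_angle`.
#' @examples
#' layout <- build_layout()
#' nrow(layout$positions)    # 46
#' layout$field_half_angle   # 11.5
#' @export
build_layout <- function(layer_spacing = 2,
                         flicker_diameter = 3,
                         ring_counts = c(3L, 6L, 9L, 12L, 15L),
                         angular_offsets = NULL) {
  stopifnot(length(layer_spacing) == 1, layer_spacing > 0,
            length(flicker_diameter) == 1, flicker_diameter > 0,
            length(ring_counts) >= 1, all(ring_counts >= 1))
  ring_counts <- as.integer(ring_counts)
  n_rings <- length(ring_counts)
  if (is.null(angular_offsets)) {
    angular_offsets <- vapply(ring_counts, function(n) {
      off <- (360 / n) / 2
      repeat {
        ang <- (off + (seq_len(n) - 1) * 360 / n) %% 90
        if (all(pmin(ang, 90 - ang) > 1e-9)) return(off)
        off <- off / 2
        if (off < 1e-6) stop("no meridian-avoiding offset found for ring")
      }
    }, numeric(1))
  }
  stopifnot(length(angular_offsets) == n_rings)

  radii <- layer_spacing * seq_len(n_rings)
  # within-ring overlap check: chord between angular neighbours
  for (k in seq_len(n_rings)) {
    if (ring_counts[k] > 1) {
      chord <- 2 * radii[k] * sin(pi / ring_counts[k])
      if (chord < flicker_diameter - 1e-9) {
        stop(sprintf(
          "ring %d (layer %d): %d stimuli at eccentricity %g leave a chord of %.3f deg between neighbours, less than the flicker diameter %g deg",
          k, k + 1L, ring_counts[k], radii[k], chord, flicker_diameter))
      }
    }
  }

  xs <- 0; ys <- 0; layer <- 1L
  for (k in seq_len(n_rings)) {
    n <- ring_counts[k]
    ang <- (angular_offsets[k] + (seq_len(n) - 1) * 360 / n) * pi / 180
    xs <- c(xs, radii[k] * cos(ang))
    ys <- c(ys, radii[k] * sin(ang))
    layer <- c(layer, rep(k + 1L, n))
  }
  positions <- cbind(x = xs, y = ys)
  structure(list(
    positions = positions,
    layer = layer,
    flicker_diameter = flicker_diameter,
    layer_spacing = layer_spacing,
    ring_counts = ring_counts,
    radii = c(0, radii),
    field_half_angle = max(radii) + flicker_diameter / 2
  ), class = "ssvep_layout")
}

#' @export
print.ssvep_layout <- function(x, ...) {
  cat(sprintf(
    "Flicker layout: %d stimuli in %d layers (spacing %g deg, flicker %g deg, field half-angle %g deg)\n",
    nrow(x$positions), length(x$ring_counts) + 1L,
    x$layer_spacing, x$flicker_diameter, x$field_half_angle))
  invisible(x)
}

#' Classify a stimulus position by layer, hemifield and vertical field
#'
#' @param layout An `ssvep_layout`.
#' @param stimulus_index Stimulus index (1 is the central flicker).
#' @param tol Numeric tolerance for treating a coordinate as on-axis.
#' @return A list with `layer` (integer), `hemifield`
#'   (`"left"`, `"right"` or `"on-axis"`) and `vertical_field`
#'   (`"lower"`, `"upper"` or `"on-axis"`).
#' @export
classify_position <- function(layout, stimulus_index, tol = 1e-9) {
  stopifnot(inherits(layout, "ssvep_layout"))
  n <- nrow(layout$positions)
  if (length(stimulus_index) != 1 || is.na(stimulus_index) ||
      stimulus_index < 1 || stimulus_index > n) {
    stop(sprintf("stimulus_index must be in 1..%d", n))
  }
  p <- layout$positions[stimulus_index, ]
  ecc <- sqrt(sum(p^2))
  layer <- which.min(abs(layout$radii - ecc))
  hemifield <- if (p[["x"]] < -tol) "left" else if (p[["x"]] > tol) "right" else "on-axis"
  vertical <- if (p[["y"]] < -tol) "lower" else if (p[["y"]] > tol) "upper" else "on-axis"
  list(layer = as.integer(layer), hemifield = hemifield, vertical_field = vertical)
}

#' Layout as a table
#'
#' Serializes a layout to the interchange table used on disk: one row per
#' stimulus with coordinates and classification labels.
#'
#' @param x An `ssvep_layout`.
#' @param ... Unused.
#' @return A data frame with columns `index`, `x_deg`, `y_deg`, `layer`,
#'   `hemifield`, `vertical_field`.
#' @export
as.data.frame.ssvep_layout <- function(x, ...) {
  n <- nrow(x$positions)
  cls <- lapply(seq_len(n), function(i) classify_position(x, i))
  data.frame(
    index = seq_len(n),
    x_deg = x$positions[, "x"],
    y_deg = x$positions[, "y"],
    layer = vapply(cls, `[[`, integer(1), "layer"),
    hemifield = vapply(cls, `[[`, character(1), "hemifield"),
    vertical_field = vapply(cls, `[[`, character(1), "vertical_field"),
    row.names = NULL
  )
}

#' Write / read a layout table
#'
#' `write_layout()` stores the serialized table as comma-separated text with
#' a header comment carrying the scalar geometry (flicker diameter, layer
#' spacing); `read_layout()` reconstructs the `ssvep_layout` so that a
#' rebuild-from-disk round trip is the identity.
#'
#' @param layout An `ssvep_layout`.
#' @param path File path.
#' @return `read_layout()` returns an `ssvep_layout`.
#' @export
write_layout <- function(layout, path) {
  df <- as.data.frame(layout)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flicker_diameter=%.17g layer_spacing=%.17g",
                     layout$flicker_diameter, layout$layer_spacing), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#")) stop("missing layout header comment")
  grab <- function(key) {
    m <- regexec(paste0(key, "=([0-9.eE+-]+)"), header)[[1]]
    if (m[1] < 0) stop(sprintf("layout header lacks %s", key))
    as.numeric(substr(header, m[2], m[2] + attr(m, "match.length")[2] - 1))
  }
  flicker_diameter <- grab("flicker_diameter")
  layer_spacing <- grab("layer_spacing")
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("index", "x_deg", "y_deg", "layer") %in% names(df)))
  df <- df[order(df$index), ]
  ecc <- sqrt(df$x_deg^2 + df$y_deg^2)
  n_rings <- max(df$layer) - 1L
  ring_counts <- as.integer(tabulate(df$layer, nbins = n_rings + 1L)[-1])
  structure(list(
    positions = cbind(x = df$x_deg, y = df$y_deg),
    layer = as.integer(df$layer),
    flicker_diameter = flicker_diameter,
    layer_spacing = layer_spacing,
    ring_counts = ring_counts,
    radii = layer_spacing * (0:n_rings),
    field_half_angle = layer_spacing * n_rings + flicker_diameter / 2
  ), class = "ssvep_layout")
}

#' Stimulus indices of a layer or hemifield
#'
#' Convenience selectors over a layout: `stimuli_in_layer()` returns the
#' indices on one ring, `stimuli_within()` all off-center stimuli with
#' eccentricity up to `d` degrees, optionally restricted to one hemifield.
#'
#' @param layout An `ssvep_layout`.
#' @param layer Layer number (1 = central flicker).
#' @param d Maximum eccentricity in degrees (inclusive, with tolerance).
#' @param side Optional hemifield filter: `"left"` or `"right"`.
#' @return Integer vector of stimulus indices.
#' @export
stimuli_in_layer <- function(layout, layer) {
  which(layout$layer == layer)
}

#' @rdname stimuli_in_layer
#' @export
stimuli_within <- function(layout, d, side = NULL) {
  ecc <- sqrt(rowSums(layout$positions^2))
  idx <- which(ecc > 1e-9 & ecc <= d + 1e-9)
  if (!is.null(side)) {
    side <- match.arg(side, c("left", "right"))
    hemi <- vapply(idx, function(i) classify_position(layout, i)$hemifield,
                   character(1))
    idx <- idx[hemi == side]
  }
  idx
}
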