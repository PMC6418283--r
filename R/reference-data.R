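#' Published per-participant error rates
#'
#' The central-versus-peripheral error rates (percent) reported for the
#' eight participants of the gaze-restricted SSVEP mapping experiment this
#' package models, one column per visual angle (2-10 degrees). Shipped as a
#' plain-text fixture; used to exercise the table-aggregation routines
#' (their across-participant average reproduces the published AVE row:
#' 11.55, 5.30, 2.08, 2.08, 2.08).
#'
#' @return Data frame with columns `participant`, `deg2`, `deg4`, `deg6`,
#'   `deg8`, `deg10`.
#' @examples
#' average_error_rates(reference_error_rates()[, -1])
#' @export
reference_error_rates <- function() {
  utils::read.csv(system.file("extdata", "reference_error_rates.csv",
                              package = "ssvepmap"))
}
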