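#' Turnover frequency from a model-reaction outcome
#'
#' The experimental response used throughout the screening campaign is the
#' turnover frequency of the model reductive-alkylation reaction,
#' \deqn{\mathrm{TOF} = \frac{\mathrm{yield}}{\mathrm{loading} \times t}
#' \quad [\mathrm{h}^{-1}],}
#' i.e. moles of product per mole of catalyst per hour. A 50% yield at
#' 5 mol% catalyst loading after 6 h gives TOF = 1.67 h^-1 (2-decimal
#' presentation).
#'
#' Full precision is retained internally; round only for presentation with
#' [round_tof()].
#'
#' @param yield_fraction Product yield as a fraction in \[0, 1\].
#' @param loading_fraction Catalyst loading as a mole fraction of the
#'   substrate (0.05 for 5 mol%). Must be positive.
#' @param time_h Reaction time in hours. Must be positive.
#' @return Turnover frequency in h^-1. Vectorised with recycling.
#' @examples
#' compute_tof(0.50, 0.05, 6) # 1.666...
#' round_tof(compute_tof(0.50, 0.05, 6)) # 1.67
#' @seealso [as_experiments()] which derives TOF for whole experiment tables.
#' @export
compute_tof <- function(yield_fraction, loading_fraction, time_h) {
  if (!is.numeric(yield_fraction) || !is.numeric(loading_fraction) ||
      !is.numeric(time_h)) {
    stopf("compute_tof(): all arguments must be numeric")
  }
  if (any(!is.finite(yield_fraction)) || any(!is.finite(loading_fraction)) ||
      any(!is.finite(time_h))) {
    stopf("compute_tof(): all arguments must be finite")
  }
  if (any(yield_fraction < 0 | yield_fraction > 1)) {
    stopf("compute_tof(): yield_fraction must lie in [0, 1]")
  }
  if (any(loading_fraction <= 0)) {
    stopf("compute_tof(): loading_fraction must be positive")
  }
  if (any(time_h <= 0)) {
    stopf("compute_tof(): time_h must be positive")
  }
  yield_fraction / (loading_fraction * time_h)
}

#' @rdname compute_tof
#' @param tof Turnover frequency values to round for presentation.
#' @param digits Decimal places (default 2, the reporting convention).
#' @export
round_tof <- function(tof, digits = 2L) {
  round_half_up(tof, digits)
}
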