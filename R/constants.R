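#' Decay constants for the 230Th/U chronometer
#'
#' Builds the pair of decay constants used throughout the U-series and
#' US-ESR age calculations. Defaults are the half-lives of Cheng et al.
#' conventionally used for speleothem dating: 75,690 yr for 230Th and
#' 245,250 yr for 234U.
#'
#' @param half_life_230 Half-life of 230Th in years.
#' @param half_life_234 Half-life of 234U in years.
#'
#' @return An object of class `decay_constants`: a list with
#'   `half_life_230`, `half_life_234`, `lambda_230`, `lambda_234`
#'   (decay constants in 1/yr).
#' @examples
#' k <- decay_constants()
#' k$lambda_230 # ~ 9.158e-06
#' @export
decay_constants <- function(half_life_230 = 75690, half_life_234 = 245250) {
  check_scalar(half_life_230, "half_life_230", lower = .Machine$double.eps)
  check_scalar(half_life_234, "half_life_234", lower = .Machine$double.eps)
  k <- list(
    half_life_230 = half_life_230,
    half_life_234 = half_life_234,
    lambda_230 = log(2) / half_life_230,
    lambda_234 = log(2) / half_life_234
  )
  if (k$lambda_230 <= k$lambda_234) {
    abort("lambda_230 must exceed lambda_234 (230Th is shorter-lived than 234U)")
  }
  class(k) <- "decay_constants"
  k
}

#' Dose-rate conversion factors for sediment radioelements
#'
#' Infinite-matrix dry dose-rate conversion factors (Guerin-style), used by
#' the external gamma geometry model. Units: mGy/kyr per ppm (U, Th) or per
#' percent (K).
#'
#' @return Named list with `gamma` and `beta` components, each holding
#'   `u_ppm`, `th_ppm`, `k_pct` factors.
#' @export
dose_conversion_factors <- function() {
  list(
    gamma = list(u_ppm = 113, th_ppm = 48.3, k_pct = 243),
    beta = list(u_ppm = 146, th_ppm = 27.7, k_pct = 782)
  )
}
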