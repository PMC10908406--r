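#' Unit conversion constants
#'
#' The package works in strict SI units internally (Pa, m, s, kg).  Clinical
#' units (mmHg, mL, L/min) appear only at input/output boundaries; these
#' constants define the conversions used throughout.
#'
#' @format `MMHG_PA` is the pressure of one millimetre of mercury in pascal
#'   (133.322 Pa).  `ML_M3` converts millilitres to cubic metres (1e-6).
#'   `LMIN_M3S` converts litres per minute to cubic metres per second.
#' @name units
NULL

#' @rdname units
#' @export
MMHG_PA <- 133.322

#' @rdname units
#' @export
ML_M3 <- 1e-6

#' @rdname units
#' @export
LMIN_M3S <- 1e-3 / 60

#' Convert pressure between mmHg and Pa
#'
#' @param x numeric vector of pressures.
#' @return converted numeric vector.
#' @export
mmHg_to_Pa <- function(x) x * MMHG_PA

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(x) x / MMHG_PA
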