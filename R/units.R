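# Energy units: kcal/mol internally; kJ-based inputs (GROMACS convention)
# converted at module boundaries with the exact factor 4.184.
# Coordinates: Angstrom internally; reaction coordinates: nm.

#' Physical constants and unit conversions
#'
#' The gas constant used throughout is `R = 0.0019872` kcal mol^-1 K^-1;
#' kJ/kcal conversion uses the exact factor 4.184. Force constants arriving
#' in kJ mol^-1 nm^-2 (the usual umbrella-sampling convention) are converted
#' once, at the estimator boundary.
#'
#' @param x Numeric vector of energies.
#' @return Converted numeric vector.
#' @examples
#' kj_to_kcal(4.184)  # 1
#' @name units
NULL

GAS_CONSTANT_KCAL <- 0.0019872 # kcal mol^-1 K^-1
KJ_PER_KCAL <- 4.184

#' @rdname units
#' @export
kj_to_kcal <- function(x) x / KJ_PER_KCAL

#' @rdname units
#' @export
kcal_to_kj <- function(x) x * KJ_PER_KCAL

#' Thermal energy RT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return RT in kcal/mol.
#' @export
rt_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  GAS_CONSTANT_KCAL * temperature
}
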