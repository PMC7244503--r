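#' Physical constants and unit conversions
#'
#' All duplex free energies are handled internally in kcal/mol at a stated
#' temperature; landscape free energies are expressed in units of the thermal
#' energy kB*T. A single gas constant is used throughout the package so that
#' the kcal/mol <-> kB*T conversion is consistent everywhere.
#'
#' @name tmsd-units
NULL

# gas constant, kcal / (mol K)
.R_KCAL <- 1.98720425864083e-3

# reference temperature of the parameter tables, Kelvin
.T_REF_K <- 310.15

#' Convert Celsius to Kelvin
#' @param temperature_c temperature in degrees Celsius
#' @return temperature in Kelvin
#' @export
celsius_to_kelvin <- function(temperature_c) temperature_c + 273.15

#' Thermal energy kB*T in kcal/mol
#'
#' @param temperature_c temperature in degrees Celsius (default 25)
#' @return kcal/mol corresponding to one unit of kB*T
#' @examples
#' kcal_per_kbt(25) # ~0.593
#' @export
kcal_per_kbt <- function(temperature_c = 25) {
  .R_KCAL * celsius_to_kelvin(temperature_c)
}

#' Convert a free energy in kcal/mol to kB*T units
#' @param dg_kcal free energy in kcal/mol
#' @param temperature_c temperature in degrees Celsius
#' @return free energy in kB*T
#' @export
kcal_to_kbt <- function(dg_kcal, temperature_c = 25) {
  dg_kcal / kcal_per_kbt(temperature_c)
}
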