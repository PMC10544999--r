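#' Physical constants and unit conversions
#'
#' The package works in the spectroscopist's unit system throughout: energies
#' and frequencies in wavenumbers (cm^-1), transition dipoles in Debye,
#' distances in Angstrom, times in femtoseconds and temperatures in Kelvin.
#' These helpers centralize the few conversion factors needed to mix them.
#'
#' @name units
NULL

## Boltzmann constant in cm^-1 per Kelvin (k_B / h c)
KB_CM1 <- 0.6950348004

## speed of light in cm per fs
C_CM_FS <- 2.99792458e-5

## angular frequency (rad/fs) per wavenumber (cm^-1): 2 pi c
CM1_TO_RADFS <- 2 * pi * C_CM_FS

#' Thermal energy in wavenumbers
#'
#' @param temperature Temperature in Kelvin.
#' @return k_B T in cm^-1 (208.5 cm^-1 at 300 K).
#' @export
#' @examples
#' kT_cm1(300)
kT_cm1 <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB_CM1 * temperature
}

#' Convert a wavenumber to an angular frequency
#'
#' @param wavenumber Energy/frequency in cm^-1.
#' @return Angular frequency in rad/fs.
#' @export
cm1_to_radfs <- function(wavenumber) CM1_TO_RADFS * wavenumber
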