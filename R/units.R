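# Unit conventions: energies and frequencies in wavenumbers (cm^-1), time in
# picoseconds, hbar = 1.  A quantity E in cm^-1 corresponds to an angular
# frequency E * cm1_to_radps in rad/ps, so every dynamical phase is
# exp(-i * cm1_to_radps * E * t).

#' Physical constants of the package unit system
#'
#' All energies and frequencies are expressed in wavenumbers (cm^-1) and time
#' in picoseconds, with hbar = 1.  `cm1_to_radps` converts an energy in cm^-1
#' to an angular frequency in rad/ps (2 pi c with c in cm/ps); `kB_cm1`
#' is the Boltzmann constant in cm^-1 per kelvin.
#'
#' @format A named list with elements `cm1_to_radps`, `kB_cm1` and
#'   `c_cm_per_ps`.
#' @examples
#' exciton_units$kB_cm1 * 300  # thermal energy at 300 K in cm^-1
#' @export
exciton_units <- local({
  c_cm_per_ps <- 0.0299792458
  list(
    c_cm_per_ps = c_cm_per_ps,
    cm1_to_radps = 2 * pi * c_cm_per_ps,
    kB_cm1 = 0.6950348004
  )
})

# internal shorthands
.kappa <- exciton_units$cm1_to_radps
.kB <- exciton_units$kB_cm1

#' Inverse temperature in 1/cm^-1
#'
#' @param temperature Temperature in kelvin.
#' @return beta = 1/(kB T) in (cm^-1)^-1.
#' @export
beta_cm1 <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1 / (.kB * temperature)
}
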