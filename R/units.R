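#' Physical constants and unit conversions
#'
#' The package works in a fixed unit system throughout: energies in
#' electron-volts (eV), temperatures in kelvin (K), times in picoseconds (ps),
#' lengths in nanometres (nm), and masses in atomic mass units (u).
#'
#' * `kB_eV`: Boltzmann constant, eV/K.
#' * `eV_per_u_nm2_ps2`: one u nm^2 ps^-2 expressed in eV (the natural kinetic
#'   energy unit of an MD velocity dump).
#'
#' @name units
#' @keywords internal
NULL

#' @rdname units
#' @export
kB_eV <- 8.617333262e-5

#' @rdname units
#' @export
eV_per_u_nm2_ps2 <- 1.66053906660e-21 / 1.602176634e-19

#' Convert between per-residue kinetic energy and kinetic temperature
#'
#' Equipartition links the kinetic energy of a residue with `dof` unconstrained
#' degrees of freedom to a kinetic temperature: `E = (dof/2) * kB * T`. The two
#' functions are exact inverses.
#'
#' @param temperature Kinetic temperature, K.
#' @param energy Kinetic energy, eV.
#' @param dof Degrees of freedom (3 per atom by default elsewhere).
#' @return `energy_from_temperature()` returns eV; `temperature_from_energy()`
#'   returns K. Both recycle arguments elementwise.
#' @examples
#' energy_from_temperature(300, dof = 39)
#' temperature_from_energy(energy_from_temperature(300, 39), 39)
#' @export
energy_from_temperature <- function(temperature, dof) {
  (dof / 2) * kB_eV * temperature
}

#' @rdname energy_from_temperature
#' @export
temperature_from_energy <- function(energy, dof) {
  2 * energy / (dof * kB_eV)
}
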