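# Unit system: length nm, energy kcal/mol, mass amu, time ps, charge e.
# 1 amu nm^2/ps^2 = 1 kJ/mol, hence the 4.184 factors below.

#' Physical constants used throughout the package
#'
#' The unit contract is: lengths in nm, energies in kcal/mol, masses in amu,
#' times in ps, charges in elementary charges. In these units
#' 1 amu nm^2 ps^-2 equals 1 kJ/mol, so kinetic energy in kcal/mol is
#' `0.5 * m * v^2 / 4.184`.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal/(mol K).}
#'   \item{coulomb}{Coulomb prefactor \eqn{e^2/(4\pi\epsilon_0)} in
#'     kcal nm/mol, i.e. the vacuum energy of two unit charges at 1 nm.}
#'   \item{kcal_per_kj}{kcal per kJ.}
#'   \item{acc_unit}{Conversion from force in kcal/(mol nm) over mass in amu
#'     to acceleration in nm/ps^2 (= 4.184).}
#' }
#' @export
cg_constants <- list(
  kB          = 0.0019872041,
  coulomb     = 138.935458 / 4.184,  # 33.2064 kcal nm / mol
  kcal_per_kj = 1 / 4.184,
  acc_unit    = 4.184
)

# kinetic energy (kcal/mol) of a velocity matrix given per-bead masses
.kinetic_energy <- function(vel, mass) {
  0.5 * sum(mass * rowSums(vel^2)) * cg_constants$kcal_per_kj
}
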