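# Physical constants in the package-wide unit system:
# length A, energy kcal/mol, charge e, mass amu, time ps, temperature K.

#' Physical constants used throughout the package
#'
#' A named list of the constants fixed by the package's unit system
#' (angstrom, kcal/mol, elementary charge, amu, ps, kelvin).
#'
#' @format Named list with elements:
#' \describe{
#'   \item{coulomb}{Electrostatic conversion factor, 332.0637 kcal A / (mol e^2).}
#'   \item{kB}{Boltzmann constant, kcal/(mol K).}
#'   \item{R_cal}{Gas constant, cal/(mol K).}
#'   \item{born}{Born self-energy prefactor, 166.03185 kcal A / (mol e^2)
#'     (half the Coulomb factor).}
#'   \item{freq_conv}{Converts a mass-weighted Hessian eigenvalue in
#'     kcal/(mol A^2 amu) to angular frequency squared in s^-2.}
#'   \item{c_cm}{Speed of light in cm/s.}
#'   \item{h}{Planck constant in J s.}
#'   \item{kB_J}{Boltzmann constant in J/K.}
#'   \item{amu_kg}{Atomic mass unit in kg.}
#' }
#' @export
bindfe_constants <- list(
  coulomb   = 332.0637,
  kB        = 0.0019872041,   # kcal/(mol K)
  R_cal     = 1.9872041,      # cal/(mol K)
  born      = 332.0637 / 2,
  # kcal/mol/A^2/amu -> s^-2:  4184 J per kcal, /NA per molecule, /amu, *1e20 A^-2->m^-2
  freq_conv = 4184 / (6.02214076e23 * 1.66053906660e-27) * 1e20,
  c_cm      = 2.99792458e10,
  h         = 6.62607015e-34,
  kB_J      = 1.380649e-23,
  amu_kg    = 1.66053906660e-27
)
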