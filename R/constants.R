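## Physical constants. Energies are kJ/mol internally (Gromacs convention);
## kcal only at reporting boundaries, converted with 1 kcal = 4.184 kJ exactly.

#' Physical constants used throughout the package
#'
#' Boltzmann constant in Gromacs units, SI constants for the Schlitter
#' entropy, and the exact thermochemical calorie.
#'
#' @format Named numeric values:
#' \describe{
#'   \item{kB_kJ}{Boltzmann constant, kJ/(mol K) (Gromacs value).}
#'   \item{kB_SI}{Boltzmann constant, J/K.}
#'   \item{hbar_SI}{Reduced Planck constant, J s.}
#'   \item{amu_kg}{Atomic mass unit, kg.}
#'   \item{avogadro}{Avogadro's number, 1/mol.}
#'   \item{kcal_kJ}{kJ per thermochemical kcal (exact).}
#' }
#' @name constants
NULL

.kB_kJ <- 0.0083144621        # kJ/(mol K), Gromacs constant
.kB_SI <- 1.380649e-23        # J/K
.hbar_SI <- 1.054571817e-34   # J s
.amu_kg <- 1.66053906660e-27  # kg
.avogadro <- 6.02214076e23    # 1/mol
.kcal_kJ <- 4.184             # exact

#' Inverse temperature in (kJ/mol)^-1
#' @param temperature Temperature in K; must be > 0.
#' @return beta = 1/(kB T) in mol/kJ.
#' @export
beta_kJ <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a single finite value > 0 (K)")
  1 / (.kB_kJ * temperature)
}

#' Convert kJ/mol to kcal/mol
#' @param x Energy in kJ/mol.
#' @return Energy in kcal/mol.
#' @export
kj_to_kcal <- function(x) x / .kcal_kJ

#' Convert kcal/mol to kJ/mol
#' @param x Energy in kcal/mol.
#' @return Energy in kJ/mol.
#' @export
kcal_to_kj <- function(x) x * .kcal_kJ
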