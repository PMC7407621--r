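#' Physical constants used throughout the package
#'
#' Units are fixed package-wide: energies in kcal/mol, lengths in Angstrom,
#' times in fs, charges in elementary charge units, masses in amu.
#'
#' @format A list with elements:
#' \describe{
#'   \item{k_B}{Boltzmann constant, 1.380649e-23 J/K}
#'   \item{h}{Planck constant, 6.62607015e-34 J s}
#'   \item{R}{Gas constant, 1.987204e-3 kcal/mol/K}
#'   \item{kB_kcal}{Boltzmann constant in kcal/mol/K (equals R per molecule-mole convention)}
#'   \item{coulomb}{Coulomb constant, 332.0636 kcal A / (mol e^2)}
#'   \item{T_default}{Default assay temperature, 298.15 K}
#' }
#' @export
physical_constants <- list(
  k_B       = 1.380649e-23,
  h         = 6.62607015e-34,
  R         = 1.987204e-3,
  kB_kcal   = 1.987204259e-3,
  coulomb   = 332.0636,
  T_default = 298.15
)

#' @keywords internal
#' @useDynLib evbscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm rnorm sd setNames vcov cor
#' @importFrom utils read.delim
"_PACKAGE"
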