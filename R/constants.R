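# Physical constants (CODATA 2018) and unit conversions used throughout.
# Internal units: nm, ns, e, mV, pA, pS, kcal/mol.

.ecc_const <- list(
  e_C        = 1.602176634e-19,      # elementary charge [C]
  N_A        = 6.02214076e23,        # Avogadro constant [1/mol]
  eps0       = 8.8541878128e-12,     # vacuum permittivity [F/m]
  R_kcal     = 1.98720425864083e-3,  # gas constant [kcal/(mol K)]
  J_per_kcal = 4184,                 # thermochemical calorie
  water_molarity = 55.5              # mol/L, pure water
)

#' Physical constants used by the package
#'
#' Returns the CODATA 2018 constants and conversion factors the package
#' uses internally (elementary charge, Avogadro constant, vacuum
#' permittivity, gas constant in kcal/(mol K), J per kcal, and the molarity
#' of pure water used by [salt_concentration()]).
#'
#' @return A named list of constants.
#' @export
#' @examples
#' ecc_constants()$R_kcal
ecc_constants <- function() .ecc_const
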