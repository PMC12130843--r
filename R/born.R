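# Born-model solvation targets and Eyring-relation utilities for
# charge-scaled (ECC) ion parameterization.

#' Solvation free-energy target for a charge-scaled ion
#'
#' Under the electronic continuum correction, the electronic part of an
#' ion's solvation free energy is treated as a mean-field continuum and
#' removed from the force field. The Born model then implies that the
#' remaining, simulation-accessible part of the experimental solvation free
#' energy scales with the square of the charge-scaling factor:
#' \deqn{\Delta G_{MD} = \Delta G_{Exp} \cdot q^2.}
#' This is the target a scaled-charge ion's computed solvation free energy
#' should reproduce.
#'
#' @param dG_exp Experimental solvation free energy (kcal/mol; negative for
#'   cations).
#' @param q Charge-scaling factor, in \eqn{[0, 1]}.
#' @return Target solvation free energy in kcal/mol.
#' @seealso [born_electronic_term()] for the continuum term itself.
#' @export
#' @examples
#' born_scaled_solvation_target(-80, 0.78)  # -48.672
born_scaled_solvation_target <- function(dG_exp, q) {
  stopifnot(is.numeric(dG_exp), is.numeric(q), is.finite(dG_exp))
  if (any(q < 0 | q > 1)) {
    stop("scaling factor q must lie in [0, 1], got ", paste(q, collapse = ", "))
  }
  dG_exp * q^2
}

#' Born-model electronic (continuum) solvation term
#'
#' The part of the ion solvation free energy attributed to electronic
#' screening with dielectric constant \eqn{\varepsilon_{el} = 1/q^2}:
#' \deqn{\Delta G_{ele} = -\frac{N_A z^2 e^2}{8 \pi \varepsilon_0 r_0}
#'   \left(1 - q^2\right),}
#' converted to kcal/mol. At \eqn{q = 1} no screening is removed and the
#' term vanishes.
#'
#' @param z Ion formal charge (integer, units of e).
#' @param r0 Effective Born radius in nm; must be positive.
#' @param q Charge-scaling factor.
#' @return Electronic solvation term in kcal/mol (non-positive for q <= 1).
#' @export
#' @examples
#' born_electronic_term(z = 1, r0 = 0.2, q = 0)
born_electronic_term <- function(z, r0, q) {
  stopifnot(is.numeric(z), is.numeric(r0), is.numeric(q))
  if (any(r0 <= 0)) stop("Born radius r0 must be positive, got ", r0)
  cc <- .ecc_const
  J_per_mol <- -cc$N_A * z^2 * cc$e_C^2 /
    (8 * pi * cc$eps0 * (r0 * 1e-9)) * (1 - q^2)
  J_per_mol / cc$J_per_kcal
}

#' Barrier-height difference implied by a rate ratio (Eyring relation)
#'
#' Converts a ratio of permeation (or any kinetic) rates into the
#' corresponding free-energy barrier difference, \eqn{RT \ln(ratio)}.
#' At 310 K a 10:1 rate ratio corresponds to about 1.4 kcal/mol and a
#' 2.5:1 ratio to about 0.6 kcal/mol.
#'
#' @param rate_ratio Positive ratio of two rates.
#' @param T_K Absolute temperature in kelvin.
#' @return Barrier difference in kcal/mol.
#' @export
#' @examples
#' eyring_barrier_difference(10, 310)
eyring_barrier_difference <- function(rate_ratio, T_K) {
  stopifnot(is.numeric(rate_ratio), is.numeric(T_K))
  if (any(rate_ratio <= 0)) stop("rate_ratio must be positive")
  if (any(T_K <= 0)) stop("temperature must be positive")
  .ecc_const$R_kcal * T_K * log(rate_ratio)
}

#' Charge-scaling factor implied by an electronic dielectric constant
#'
#' The ECC prescribes scaling ionic charges by \eqn{q = \sqrt{1/\varepsilon_{el}}}
#' where \eqn{\varepsilon_{el}} is the high-frequency (electronic) dielectric
#' constant of the medium; for most organic media \eqn{\varepsilon_{el} \approx 2},
#' giving \eqn{q \approx 0.7}.
#'
#' Note the square-root relation \eqn{q^2 = 1/\varepsilon_{el}}: it is this
#' form, not \eqn{q = 1/\varepsilon_{el}}, that is consistent with the
#' \eqn{(1-q^2)} factor in [born_electronic_term()].
#'
#' @param eps_el Electronic dielectric constant, >= 1.
#' @return Dimensionless scaling factor in (0, 1].
#' @export
#' @examples
#' scaling_factor_from_dielectric(2)  # ~0.707
scaling_factor_from_dielectric <- function(eps_el) {
  stopifnot(is.numeric(eps_el))
  if (any(eps_el < 1)) stop("electronic dielectric constant must be >= 1")
  sqrt(1 / eps_el)
}
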