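# ECC charge scaling in the two force-field conventions:
#  - "group" mode (Charmm-style): multiply the charges of the charge group
#    carrying the formal charge by q;
#  - "weighted" mode (Amber-style): per-atom weighted average of the
#    charged and neutral protonation-state charge sets, weight q.

#' Default charged-group membership table
#'
#' Ships an editable table of side-chain charge groups for the standard
#' charged residues (ASP, GLU, LYS, ARG, protonated HIS) plus monatomic
#' ions, using Charmm-style atom names. The memberships are illustrative
#' defaults: each group must sum to the residue's formal charge, which
#' [scale_group_charges()] verifies, so a mismatch with your force field
#' fails loudly rather than silently.
#'
#' @param topology Optional `ecc_topology`; if given, the table is
#'   restricted to residue names actually present (so the shipped defaults
#'   can be applied to any topology without naming residues it lacks).
#' @param path Optional path to a custom two-column CSV (`residue`,
#'   `atom`); defaults to the file shipped with the package.
#' @return Named list mapping residue name to a character vector of atom
#'   names.
#' @export
default_charged_groups <- function(topology = NULL, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "charged_groups.csv", package = "eccperm")
  }
  # na.strings = "": "NA" is a legitimate sodium residue/atom name
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = "")
  stopifnot(all(c("residue", "atom") %in% names(tab)))
  groups <- split(tab$atom, tab$residue)
  if (!is.null(topology)) {
    stopifnot(inherits(topology, "ecc_topology"))
    groups <- groups[names(groups) %in% unique(topology$atoms$residue)]
  }
  groups
}

#' Scale charged-group charges by the ECC factor (Charmm convention)
#'
#' For every residue instance whose name appears in `charged_groups`, the
#' partial charges of the listed atoms (the charge group carrying the
#' formal charge, e.g. the -CH2-CO2 group of ASP) are multiplied by `q`.
#' All other atoms are untouched, so each scaled residue's net charge
#' becomes `q` times its formal charge and a neutral system stays neutral.
#' Monatomic ions are one-atom groups and are simply scaled by `q`.
#'
#' Charges are scaled at full double precision in memory; rounding to file
#' precision (with residual smearing) happens only in [write_topology()].
#'
#' @param topology An `ecc_topology` from [read_topology()].
#' @param charged_groups Named list mapping residue name to the atom names
#'   of its charged group (see [default_charged_groups()]).
#' @param q Scaling factor in (0, 1].
#' @param tol Tolerance (e) for checking that each group's charges sum to
#'   an integer formal charge before scaling.
#' @return A new `ecc_topology` with scaled charges; modified atoms are
#'   flagged internally so [write_topology()] reformats only their lines.
#' @export
#' @examples
#' top <- read_topology(system.file("extdata", "example_topology.itp",
#'                                  package = "eccperm"))
#' scaled <- scale_group_charges(top, default_charged_groups(top), q = 0.78)
#' sum(scaled$atoms$charge) / sum(top$atoms$charge)  # = 0.78 if fully ionic
scale_group_charges <- function(topology, charged_groups, q, tol = 1e-4) {
  stopifnot(inherits(topology, "ecc_topology"), is.list(charged_groups))
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 1) {
    stop("scaling factor q must be a single value in (0, 1], got ", q)
  }
  a <- topology$atoms
  unknown <- setdiff(names(charged_groups), unique(a$residue))
  if (length(unknown) > 0) {
    stop("charged_groups names residue(s) absent from the topology: ",
         paste(unknown, collapse = ", "),
         " (use default_charged_groups(topology) to restrict to present residues)")
  }
  modified <- topology$modified
  for (res_name in names(charged_groups)) {
    members <- charged_groups[[res_name]]
    res_rows <- which(a$residue == res_name)
    for (key in unique(paste(a$molblock[res_rows], a$resnr[res_rows]))) {
      parts <- strsplit(key, " ")[[1]]
      idx <- res_rows[a$molblock[res_rows] == as.integer(parts[[1]]) &
                        a$resnr[res_rows] == as.integer(parts[[2]])]
      gidx <- idx[a$atom[idx] %in% members]
      if (length(gidx) == 0) {
        stop("residue ", res_name, " (resnr ", parts[[2]],
             "): none of the listed charged-group atoms found")
      }
      gsum <- sum(a$charge[gidx])
      if (abs(gsum - round(gsum)) > tol) {
        stop(sprintf(
          "residue %s (resnr %s): charged-group sum %.6f e is not integral (tol %g)",
          res_name, parts[[2]], gsum, tol))
      }
      a$charge[gidx] <- a$charge[gidx] * q
      modified[gidx] <- TRUE
    }
  }
  out <- topology
  out$atoms <- a
  out$modified <- modified
  out
}

#' Weighted-average charge scaling (Amber convention)
#'
#' In force fields where the unit charge is distributed over the backbone
#' as well as the side chain, group scaling is not possible; instead the
#' scaled charge of every atom is the weighted average of its charged
#' (protonation-state) and neutral-state charges with the scaling factor
#' as the weight: \eqn{q_i^{scaled} = q \cdot q_i^{charged} + (1-q) \cdot
#' q_i^{neutral}}. Because the charged state sums to the formal charge
#' (+-1) and the neutral state to zero, the residue's net charge becomes
#' exactly `q` times the formal charge.
#'
#' @param charged_state Named numeric vector of per-atom charges of the
#'   ionized form (names = atom names); must sum to +-1 within `tol`.
#' @param neutral_state Named numeric vector for the neutral form over the
#'   same atoms; must sum to 0 within `tol`.
#' @param q Scaling factor in (0, 1].
#' @param tol Tolerance (e) on the state net charges.
#' @return Named numeric vector of scaled charges, in the order of
#'   `charged_state`.
#' @export
#' @examples
#' scale_weighted_charges(c(OD1 = -0.80), c(OD1 = -0.60), q = 0.75)  # -0.75
scale_weighted_charges <- function(charged_state, neutral_state, q, tol = 1e-4) {
  stopifnot(is.numeric(charged_state), is.numeric(neutral_state))
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 1) {
    stop("scaling factor q must be a single value in (0, 1], got ", q)
  }
  if (is.null(names(charged_state)) || is.null(names(neutral_state))) {
    stop("both charge states must be named by atom")
  }
  if (!setequal(names(charged_state), names(neutral_state)) ||
      anyDuplicated(names(charged_state)) || anyDuplicated(names(neutral_state))) {
    stop("atom-name mismatch between charged and neutral states")
  }
  neutral_state <- neutral_state[names(charged_state)]
  s_charged <- sum(charged_state)
  if (abs(abs(s_charged) - 1) > tol) {
    stop(sprintf("charged state must sum to +-1 e, sums to %.6f", s_charged))
  }
  if (abs(sum(neutral_state)) > tol) {
    stop(sprintf("neutral state must sum to 0 e, sums to %.6f",
                 sum(neutral_state)))
  }
  q * charged_state + (1 - q) * neutral_state
}

#' Interpolate an ion Lennard-Jones sigma between optimized anchors
#'
#' Radius-corrected ion LJ parameters are optimized on a coarse grid of
#' scaling factors (every 0.05 step from 1.00) so that the first
#' solvation-shell radius reproduces the unscaled force field; sigma at
#' intermediate scaling factors is obtained by piecewise-linear
#' interpolation between the bracketing anchors. Epsilon is never
#' interpolated or modified. No extrapolation outside the anchor range.
#'
#' @param table Data frame with columns `q_anchor` and `sigma` (nm), e.g.
#'   from [read_sigma_anchors()].
#' @param q Scaling factor(s) at which sigma is required.
#' @return Sigma in nm (vectorized over `q`); exact at anchors.
#' @export
interpolate_ion_sigma <- function(table, q) {
  stopifnot(is.data.frame(table), all(c("q_anchor", "sigma") %in% names(table)))
  if (any(table$sigma <= 0)) stop("anchor sigma values must be positive")
  if (anyDuplicated(table$q_anchor)) stop("duplicate anchor scaling factors")
  if (any(q < min(table$q_anchor) - 1e-12 | q > max(table$q_anchor) + 1e-12)) {
    stop(sprintf("q outside the anchor range [%g, %g]; extrapolation is not allowed",
                 min(table$q_anchor), max(table$q_anchor)))
  }
  stats::approx(table$q_anchor, table$sigma, xout = q, rule = 1)$y
}

#' Read an ion sigma-anchor table
#'
#' Reads a CSV with columns `ion`, `q_anchor`, `sigma` (nm) and optionally
#' `epsilon` (kJ/mol, constant across anchors). The package ships a
#' synthetic illustrative example (`sigma_anchors_example.csv`); real
#' optimized values are force-field specific and supplied by the user.
#'
#' @param path CSV path.
#' @param ion Optional ion name to filter on (e.g. "K").
#' @return Data frame of anchors sorted by decreasing `q_anchor`.
#' @export
read_sigma_anchors <- function(path, ion = NULL) {
  # na.strings = "": "NA" is a legitimate sodium ion name
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = "")
  stopifnot(all(c("ion", "q_anchor", "sigma") %in% names(tab)))
  if (!is.null(ion)) {
    tab <- tab[tab$ion == ion, ]
    if (nrow(tab) == 0) stop("no anchors for ion ", ion, " in ", path)
  }
  if ("epsilon" %in% names(tab) && length(unique(tab$epsilon)) > length(unique(tab$ion))) {
    stop("epsilon must be constant per ion (it is never interpolated)")
  }
  tab[order(-tab$q_anchor), ]
}
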