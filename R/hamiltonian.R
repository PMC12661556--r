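#' Four-way energy decomposition of a configuration
#'
#' The potential energy of a solute/solvent system is split into the four
#' terms the scaled Hamiltonians act on: `epp1`, the scalable solute
#' intramolecular energy (LJ, Coulomb, proper torsions); `epp2`, the
#' unscaled solute intramolecular energy (bonds, angles, improper torsions,
#' and any excluded proper torsions); `epw`, the solute-solvent interaction
#' energy; and `eww`, the solvent intramolecular energy.
#'
#' @param epp1,epp2,epw,eww Finite energies in a common unit system.
#' @return An object of class `energy_decomp` (a named list).
#' @export
energy_decomposition <- function(epp1, epp2 = 0, epw = 0, eww = 0) {
  vals <- c(epp1 = epp1, epp2 = epp2, epw = epw, eww = eww)
  if (!all(is.finite(vals))) stop("energy decomposition must be finite")
  structure(as.list(vals), class = "energy_decomp")
}

#' @export
print.energy_decomp <- function(x, ...) {
  cat(sprintf("E_pp1 = %g, E_pp2 = %g, E_pw = %g, E_ww = %g\n",
              x$epp1, x$epp2, x$epw, x$eww))
  invisible(x)
}

#' Coefficients of the method-scaled Hamiltonian
#'
#' Every supported effective Hamiltonian is linear in the four decomposition
#' terms; this returns the coefficient vector `(c_pp1, c_pp2, c_pw, c_ww)`
#' for a rung with scaling factor `lam` (= beta_m/beta_ref):
#' \describe{
#'   \item{sst2}{\eqn{\lambda, 1, \sqrt\lambda, 1} — solute scaled, bonded
#'     backbone terms untouched, solute-solvent by \eqn{\sqrt\lambda}
#'     (consistent with charge scaling by \eqn{\sqrt\lambda}).}
#'   \item{rest2}{\eqn{\lambda, \lambda, \sqrt\lambda, 1} — the whole solute
#'     intramolecular energy scaled.}
#'   \item{sst1}{the REST form: solute untouched, solute-solvent by
#'     \eqn{(\beta_{ref}+\beta_m)/(2\beta_m)}, solvent by
#'     \eqn{\beta_{ref}/\beta_m}.}
#'   \item{st}{\eqn{1, 1, 1, 1} — plain potential; tempering acts through
#'     the simulation temperature, not the Hamiltonian.}
#' }
#'
#' @param method One of `"st"`, `"sst1"`, `"sst2"`, `"rest2"`.
#' @param lam Scaling factor \eqn{\lambda_m = \beta_m/\beta_{ref}}.
#' @return Numeric vector of length 4, names `c("epp1","epp2","epw","eww")`.
#' @export
hamiltonian_coefficients <- function(method, lam) {
  if (lam <= 0) stop("invalid scaling factor")
  switch(method,
    sst2  = c(epp1 = lam, epp2 = 1, epw = sqrt(lam), eww = 1),
    rest2 = c(epp1 = lam, epp2 = lam, epw = sqrt(lam), eww = 1),
    sst1  = ,
    rest  = {
      # lam = beta_m/beta_ref, so beta_ref/beta_m = 1/lam
      c(epp1 = 1, epp2 = 1, epw = (1 / lam + 1) / 2, eww = 1 / lam)
    },
    st    = c(epp1 = 1, epp2 = 1, epw = 1, eww = 1),
    stop("unsupported method: ", method)
  )
}

#' Method-scaled effective energy of a configuration
#'
#' Evaluates the effective Hamiltonian of rung `rung` on the unscaled
#' (\eqn{\lambda = 1}) decomposition of a configuration. For SST2 this is
#' \deqn{E_m(X) = \lambda_m E_{pp}^{(1)} + E_{pp}^{(2)} +
#'   \sqrt{\lambda_m} E_{pw} + E_{ww}.}
#'
#' @param decomp An [energy_decomposition()] evaluated with unscaled
#'   parameters.
#' @param rung,ref Rung rows (see [ladder_rung()]); `ref` is the reference
#'   rung. Only their `lam`/`beta` fields are used.
#' @param method One of `"st"`, `"sst1"`, `"sst2"`, `"rest2"`.
#' @return The scalar effective energy.
#' @export
scaled_energy <- function(decomp, rung, ref, method = "sst2") {
  co <- hamiltonian_coefficients(method, rung$lam)
  co[["epp1"]] * decomp$epp1 + co[["epp2"]] * decomp$epp2 +
    co[["epw"]] * decomp$epw + co[["eww"]] * decomp$eww
}

#' Acceptance-ratio monitor energy
#'
#' The quantity whose inter-rung distribution overlap diagnoses whether a
#' ladder is dense enough: per rung m it is
#' \eqn{E_{pp} + \tfrac12\sqrt{\beta_{ref}/\beta_m}\,E_{pw}} (default,
#' derived from the scaled Hamiltonian) or
#' \eqn{E_{pp} + \tfrac12(\beta_{ref}/\beta_m)\,E_{pw}} with
#' `variant = "printed"`.
#'
#' @inheritParams scaled_energy
#' @param variant `"radical"` (default) or `"printed"`.
#' @return The scalar monitor energy.
#' @export
monitor_energy <- function(decomp, rung, ref, variant = c("radical", "printed")) {
  variant <- match.arg(variant)
  ratio <- ref$beta / rung$beta
  coef <- if (variant == "radical") 0.5 * sqrt(ratio) else 0.5 * ratio
  decomp$epp1 + decomp$epp2 + coef * decomp$epw
}

#' Scale solute force-field parameters for one rung
#'
#' Applies the SST2/REST2 parameter-space scaling that realizes the scaled
#' Hamiltonian: solute Lennard-Jones epsilon and scaled proper-torsion force
#' constants are multiplied by \eqn{\lambda}, solute partial charges by
#' \eqn{\sqrt\lambda}. Bonds, angles, improper torsions, excluded proper
#' torsions, and all solvent parameters are untouched. With a geometric-mean
#' epsilon combination rule this reproduces pair factors \eqn{\lambda}
#' (solute-solute) and \eqn{\sqrt\lambda} (solute-solvent) exactly.
#'
#' @param params A [param_system()].
#' @param lam Positive scaling factor.
#' @param torsion_partition Optional [partition_torsions()] result; torsion
#'   terms in its `unscaled_terms` keep their force constants. By default
#'   all proper torsions are scaled.
#' @return A `param_system` with scaled parameters.
#' @export
scale_solute_parameters <- function(params, lam, torsion_partition = NULL) {
  stopifnot(inherits(params, "param_system"))
  if (lam <= 0) stop("invalid scaling factor")
  out <- params
  sol <- params$atoms$is_solute
  out$atoms$eps[sol] <- params$atoms$eps[sol] * lam
  out$atoms$charge[sol] <- params$atoms$charge[sol] * sqrt(lam)
  if (nrow(params$torsions) > 0) {
    scaled <- rep(TRUE, nrow(params$torsions))
    if (!is.null(torsion_partition)) {
      scaled <- params$torsions$term_id %in% torsion_partition$scaled_terms
    }
    out$torsions$k[scaled] <- params$torsions$k[scaled] * lam
  }
  out
}

#' Partition proper torsions into scaled and unscaled sets
#'
#' Cis-proline states can trap a peptide in an unfolded conformation for
#' long stretches of a tempering run; scaling down the omega-torsion
#' barrier makes this worse. With `exclude_omega = TRUE`, every proper
#' torsion whose middle bond (positions 2 and 3 of the four bonded atoms)
#' is C(i-1)-N(i) with residue i a proline is moved to the unscaled set,
#' i.e. kept in \eqn{E_{pp}^{(2)}} instead of \eqn{E_{pp}^{(1)}}.
#'
#' @param topology Data frame with one row per proper-torsion term and
#'   columns `term_id`, `res_index` (residue of the term's atom 3 / N-side),
#'   `res_name`, and `a1`..`a4` — the four atom names in bonded order.
#'   For the omega term of residue i the row carries atoms
#'   CA(i-1), C(i-1), N(i), CA(i) with `res_index = i`.
#' @param exclude_omega Logical flag.
#' @return A list of class `torsion_partition` with character vectors
#'   `scaled_terms` and `unscaled_terms`; disjoint, jointly exhaustive.
#' @export
partition_torsions <- function(topology, exclude_omega = FALSE) {
  needed <- c("term_id", "res_index", "res_name", "a1", "a2", "a3", "a4")
  if (!all(needed %in% names(topology))) {
    stop("malformed torsion term: topology needs columns ",
         paste(needed, collapse = ", "))
  }
  atom_cols <- topology[c("a1", "a2", "a3", "a4")]
  if (any(!vapply(atom_cols, is.character, TRUE) &
          !vapply(atom_cols, is.factor, TRUE))) {
    stop("malformed torsion term: atom names must be character")
  }
  excluded <- rep(FALSE, nrow(topology))
  if (exclude_omega && nrow(topology) > 0) {
    is_pro <- toupper(topology$res_name) %in% c("PRO", "PROLINE")
    # middle bond C(i-1)-N(i), either listing direction
    mid_cn <- (topology$a2 == "C" & topology$a3 == "N") |
              (topology$a2 == "N" & topology$a3 == "C")
    excluded <- is_pro & mid_cn
  }
  structure(
    list(scaled_terms = as.character(topology$term_id[!excluded]),
         unscaled_terms = as.character(topology$term_id[excluded])),
    class = "torsion_partition"
  )
}
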