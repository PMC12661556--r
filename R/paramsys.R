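# Minimal pairwise force field used to validate the parameter-scaling rules
# against the scaled-Hamiltonian route. Reduced units: Coulomb constant = 1.

#' Construct a minimal parameterized system
#'
#' A toy force field with pairwise Lennard-Jones (geometric-mean epsilon
#' combination — a requirement for per-atom epsilon scaling to reproduce the
#' pair factors — and arithmetic-mean sigma), pairwise Coulomb, and proper
#' cosine torsions. Atoms are flagged solute or solvent; there are no
#' exclusions or cutoffs.
#'
#' @param atoms Data frame with columns `is_solute` (logical), `eps`,
#'   `sigma`, `charge`. One row per atom.
#' @param torsions Optional data frame with columns `term_id`, `i`, `j`,
#'   `k_atom`, `l` (1-based atom indices in bonded order), `k` (force
#'   constant), `n` (periodicity), `phase` (degrees). Torsion atoms must all
#'   be solute (solvent here is an unstructured bath).
#' @return An object of class `param_system`.
#' @export
param_system <- function(atoms, torsions = NULL) {
  stopifnot(all(c("is_solute", "eps", "sigma", "charge") %in% names(atoms)))
  if (any(atoms$eps < 0)) stop("negative LJ epsilon")
  if (is.null(torsions)) {
    torsions <- data.frame(term_id = character(), i = integer(),
                           j = integer(), k_atom = integer(), l = integer(),
                           k = numeric(), n = integer(), phase = numeric())
  }
  structure(list(atoms = atoms, torsions = torsions), class = "param_system")
}

pair_energy_terms <- function(atoms, coords) {
  n <- nrow(atoms)
  if (n < 2) return(c(lj = 0, coul = 0))
  idx <- utils::combn(n, 2)
  d <- coords[idx[1, ], , drop = FALSE] - coords[idx[2, ], , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  eps <- sqrt(atoms$eps[idx[1, ]] * atoms$eps[idx[2, ]])
  sig <- (atoms$sigma[idx[1, ]] + atoms$sigma[idx[2, ]]) / 2
  sr6 <- (sig / r)^6
  lj <- sum(4 * eps * (sr6^2 - sr6))
  coul <- sum(atoms$charge[idx[1, ]] * atoms$charge[idx[2, ]] / r)
  c(lj = lj, coul = coul)
}

torsion_energy_terms <- function(torsions, coords) {
  if (nrow(torsions) == 0) return(numeric(0))
  vapply(seq_len(nrow(torsions)), function(t) {
    phi <- dihedral_angle(coords[torsions$i[t], ], coords[torsions$j[t], ],
                          coords[torsions$k_atom[t], ], coords[torsions$l[t], ])
    torsions$k[t] * (1 + cos((torsions$n[t] * phi - torsions$phase[t]) * pi / 180))
  }, numeric(1))
}

#' Total potential energy of a parameterized system
#'
#' @param sys A [param_system()].
#' @param coords Numeric matrix, one row per atom, columns x/y/z.
#' @return Scalar energy (reduced units).
#' @export
param_energy <- function(sys, coords) {
  stopifnot(inherits(sys, "param_system"), nrow(coords) == nrow(sys$atoms))
  sum(pair_energy_terms(sys$atoms, coords)) +
    sum(torsion_energy_terms(sys$torsions, coords))
}

subset_param_system <- function(sys, keep) {
  idx_map <- match(seq_len(nrow(sys$atoms)), which(keep))
  tors <- sys$torsions
  in_subset <- keep[tors$i] & keep[tors$j] & keep[tors$k_atom] & keep[tors$l]
  tors <- tors[in_subset, , drop = FALSE]
  tors$i <- idx_map[tors$i]; tors$j <- idx_map[tors$j]
  tors$k_atom <- idx_map[tors$k_atom]; tors$l <- idx_map[tors$l]
  param_system(sys$atoms[keep, , drop = FALSE], tors)
}

#' Decompose the energy of a parameterized system
#'
#' Follows the operational subsystem contract: the solute intramolecular
#' energy is evaluated on a solute-only copy of the system, the solvent
#' intramolecular energy on a solvent-only copy, and the solute-solvent
#' interaction is the remainder `E_total - E_pp - E_ww`. The solute energy
#' is then split into the scalable part `epp1` (LJ, Coulomb, and torsions in
#' the scaled partition) and the unscaled part `epp2` (excluded torsions).
#'
#' @inheritParams param_energy
#' @param torsion_partition Optional [partition_torsions()] result; terms in
#'   `unscaled_terms` are booked under `epp2`.
#' @return An [energy_decomposition()].
#' @export
decompose_param_energy <- function(sys, coords, torsion_partition = NULL) {
  stopifnot(inherits(sys, "param_system"), nrow(coords) == nrow(sys$atoms))
  sol <- sys$atoms$is_solute
  e_total <- param_energy(sys, coords)

  sys_pp <- subset_param_system(sys, sol)
  pp_pair <- pair_energy_terms(sys_pp$atoms, coords[sol, , drop = FALSE])
  pp_tors <- torsion_energy_terms(sys_pp$torsions, coords[sol, , drop = FALSE])
  e_pp <- sum(pp_pair) + sum(pp_tors)

  sys_ww <- subset_param_system(sys, !sol)
  e_ww <- param_energy(sys_ww, coords[!sol, , drop = FALSE])

  unscaled <- rep(FALSE, length(pp_tors))
  if (!is.null(torsion_partition) && length(pp_tors) > 0) {
    unscaled <- sys_pp$torsions$term_id %in% torsion_partition$unscaled_terms
  }
  epp2 <- sum(pp_tors[unscaled])
  energy_decomposition(epp1 = e_pp - epp2, epp2 = epp2,
                       epw = e_total - e_pp - e_ww, eww = e_ww)
}
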