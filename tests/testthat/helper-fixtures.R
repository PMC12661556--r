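# Shared fixtures: builders for small randomized systems and reference
# ladders used across the suite.

cln025_ladder <- function() build_ladder(280, 540, 300, 10, n_below_ref = 1)

# A one-row rung with a given lambda, for operations that only read
# lam/beta/index (beta in the reduced system of the given t_ref).
fake_rung <- function(lam, t_ref = 300, index = 0L) {
  data.frame(index = index, temperature = t_ref / lam,
             beta = lam / t_ref, lam = lam, weight = 0)
}

random_decomp <- function() {
  energy_decomposition(epp1 = stats::runif(1, -50, 150),
                       epp2 = stats::runif(1, 0, 30),
                       epw = stats::runif(1, -80, 20),
                       eww = stats::runif(1, -200, 0))
}

# Randomized LJ + Coulomb + torsion system: 4 solute atoms carrying two
# proper torsions (one of them a proline omega), 5 solvent atoms.
random_param_system <- function() {
  n_sol <- 4L; n_wat <- 5L
  atoms <- data.frame(
    is_solute = rep(c(TRUE, FALSE), c(n_sol, n_wat)),
    eps = stats::runif(n_sol + n_wat, 0.5, 1.5),
    sigma = stats::runif(n_sol + n_wat, 0.8, 1.2),
    charge = stats::runif(n_sol + n_wat, -1, 1)
  )
  torsions <- data.frame(
    term_id = c("tor_psi", "tor_omega_pro"),
    i = c(1L, 1L), j = c(2L, 2L), k_atom = c(3L, 3L), l = c(4L, 4L),
    k = stats::runif(2, 1, 5), n = c(2L, 1L), phase = c(0, 180)
  )
  param_system(atoms, torsions)
}

random_coords <- function(n) {
  # spread points out to keep LJ energies well-conditioned
  matrix(stats::runif(3 * n, 0, 4), ncol = 3) +
    3 * as.matrix(expand.grid(0:1, 0:1, 0:2))[seq_len(n), ]
}

# Topology table marking tor_omega_pro as a proline omega term.
proline_topology <- function() {
  data.frame(
    term_id = c("tor_psi", "tor_omega_pro"),
    res_index = c(2L, 2L),
    res_name = c("PRO", "PRO"),
    a1 = c("N", "CA"), a2 = c("CA", "C"), a3 = c("C", "N"),
    a4 = c("O", "CA"),
    stringsAsFactors = FALSE
  )
}

# Evaluate the 4PL sigmoid.
four_pl <- function(x, a, d, c, b) d + (a - d) / (1 + (x / c)^b)
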