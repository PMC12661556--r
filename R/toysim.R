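# Analytically tractable solute/solvent model systems and a seeded BAOAB
# Langevin integrator. Reduced units throughout: k_B = 1, unit masses.

#' Define a toy solute/solvent system
#'
#' The solute is a set of `d_solute` coordinates moving in either a
#' harmonic well (`0.5 * k_solute * x^2` per coordinate) or, for the first
#' solute coordinate, a symmetric quartic double well
#' `barrier * ((x/a)^2 - 1)^2` with minima at `+/- a = well_separation / 2`
#' and a barrier of height `barrier` at the origin (remaining solute
#' coordinates stay harmonic). The solvent is a harmonic bath of
#' `d_solvent` coordinates; solute and solvent couple through a bilinear
#' term `coupling * sum(x_i * y_i)` over the first
#' `min(d_solute, d_solvent)` pairs. The double-well coordinate doubles as
#' an RMSD-like order parameter for the analysis suite.
#'
#' @param d_solute Number of solute coordinates (>= 1).
#' @param d_solvent Number of solvent coordinates (>= 0).
#' @param potential `"harmonic"` or `"double_well"`.
#' @param k_solute,k_solvent Spring constants (> 0), reduced energy/length^2.
#' @param barrier Double-well barrier height (>= 0), reduced energy.
#' @param well_separation Distance between the two minima, reduced length.
#' @param coupling Bilinear solute-solvent coupling constant.
#' @param unscaled_solute Indices of solute coordinates whose potential
#'   terms are booked as unscaled (`epp2`); default none, i.e. the whole
#'   solute potential is scalable, mirroring the LJ/Coulomb/proper-torsion
#'   convention.
#' @return An object of class `toy_system`.
#' @export
toy_system <- function(d_solute, d_solvent = 0,
                       potential = c("harmonic", "double_well"),
                       k_solute = 1, k_solvent = 1,
                       barrier = 0, well_separation = 2,
                       coupling = 0, unscaled_solute = integer(0)) {
  potential <- match.arg(potential)
  if (d_solute < 1) stop("d_solute must be >= 1")
  if (k_solute <= 0 || k_solvent <= 0) stop("spring constants must be > 0")
  if (barrier < 0) stop("barrier must be >= 0")
  structure(
    list(d_solute = as.integer(d_solute), d_solvent = as.integer(d_solvent),
         potential = potential, k_solute = k_solute, k_solvent = k_solvent,
         barrier = barrier, well_separation = well_separation,
         coupling = coupling,
         unscaled_solute = as.integer(unscaled_solute)),
    class = "toy_system"
  )
}

n_coords <- function(system) system$d_solute + system$d_solvent

solute_term_energies <- function(system, x) {
  e <- 0.5 * system$k_solute * x^2
  if (system$potential == "double_well") {
    a <- system$well_separation / 2
    e[1] <- system$barrier * ((x[1] / a)^2 - 1)^2
  }
  e
}

#' Decompose the toy potential energy of a configuration
#'
#' @param system A [toy_system()].
#' @param coords Numeric vector of length `d_solute + d_solvent` (solute
#'   coordinates first).
#' @return An [energy_decomposition()]: `epp1` the scalable solute terms,
#'   `epp2` the terms of `unscaled_solute` coordinates, `eww` the solvent
#'   bath, `epw` the bilinear coupling (equal to the total minus the
#'   subsystem energies, mirroring the operational subsystem contract).
#' @export
decompose_energy <- function(system, coords) {
  if (length(coords) != n_coords(system)) stop("dimension error")
  ds <- system$d_solute
  x <- coords[seq_len(ds)]
  y <- if (system$d_solvent > 0) coords[ds + seq_len(system$d_solvent)] else numeric(0)
  e_sol <- solute_term_energies(system, x)
  unscaled <- seq_len(ds) %in% system$unscaled_solute
  nc <- min(ds, system$d_solvent)
  epw <- if (nc > 0) system$coupling * sum(x[seq_len(nc)] * y[seq_len(nc)]) else 0
  energy_decomposition(
    epp1 = sum(e_sol[!unscaled]),
    epp2 = sum(e_sol[unscaled]),
    epw = epw,
    eww = 0.5 * system$k_solvent * sum(y^2)
  )
}

# Gradient of the method-scaled effective potential; co is the
# hamiltonian_coefficients() vector.
effective_force <- function(system, coords, co) {
  ds <- system$d_solute
  x <- coords[seq_len(ds)]
  y <- if (system$d_solvent > 0) coords[ds + seq_len(system$d_solvent)] else numeric(0)
  g_sol <- system$k_solute * x
  if (system$potential == "double_well") {
    a <- system$well_separation / 2
    g_sol[1] <- 4 * system$barrier * x[1] * ((x[1] / a)^2 - 1) / a^2
  }
  c_sol <- ifelse(seq_len(ds) %in% system$unscaled_solute,
                  co[["epp2"]], co[["epp1"]])
  grad_x <- c_sol * g_sol
  grad_y <- if (system$d_solvent > 0) co[["eww"]] * system$k_solvent * y else numeric(0)
  nc <- min(ds, system$d_solvent)
  if (nc > 0 && system$coupling != 0) {
    ii <- seq_len(nc)
    grad_x[ii] <- grad_x[ii] + co[["epw"]] * system$coupling * y[ii]
    grad_y[ii] <- grad_y[ii] + co[["epw"]] * system$coupling * x[ii]
  }
  -c(grad_x, grad_y)
}

#' Integrator configuration
#'
#' @param timestep Integration timestep (> 0), reduced time units.
#' @param friction Langevin friction coefficient (> 0), inverse reduced
#'   time. The default of 1 mirrors the low-friction choice that gives the
#'   tempering walk good configurational mobility.
#' @param t_ref Reference temperature in reduced units (k_B = 1).
#' @param seed Optional integer seed; when set, a fresh state is started
#'   from this seed so runs are exactly reproducible.
#' @param mass Particle mass (uniform), reduced units.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(timestep = 0.01, friction = 1.0, t_ref = 1.0,
                              seed = NULL, mass = 1.0) {
  if (timestep <= 0) stop("timestep must be > 0")
  if (friction <= 0) stop("friction must be > 0")
  structure(list(timestep = timestep, friction = friction, t_ref = t_ref,
                 seed = seed, mass = mass),
            class = "integrator_config")
}

#' Initialize a simulation state
#'
#' @param system A [toy_system()].
#' @param coords Optional starting coordinates; default is the origin, with
#'   the double-well coordinate placed in its positive minimum.
#' @param velocities Optional starting velocities; default zero.
#' @return An object of class `sim_state` with fields `coords`,
#'   `velocities`, `time`, and `rng_state` (filled on first integration).
#' @export
sim_state <- function(system, coords = NULL, velocities = NULL) {
  n <- n_coords(system)
  if (is.null(coords)) {
    coords <- numeric(n)
    if (system$potential == "double_well") {
      coords[1] <- system$well_separation / 2
    }
  }
  if (is.null(velocities)) velocities <- numeric(n)
  if (length(coords) != n || length(velocities) != n) stop("dimension error")
  structure(list(coords = coords, velocities = velocities,
                 time = 0, rng_state = NULL),
            class = "sim_state")
}

#' Advance BAOAB Langevin dynamics on a scaled toy Hamiltonian
#'
#' Propagates the configuration on the effective potential of the given
#' method and scaling factor, at the given simulation temperature (the
#' reference temperature for Hamiltonian-scaled methods; the rung
#' temperature for plain simulated tempering). The BAOAB splitting is used
#' for its accurate configurational sampling at finite timestep. The random
#' stream continues from `state$rng_state` when present, otherwise it is
#' started from `cfg$seed`, so a run is fully reproducible from
#' (config, seed).
#'
#' @param system A [toy_system()].
#' @param state A [sim_state()].
#' @param cfg An [integrator_config()].
#' @param lam Hamiltonian scaling factor (> 0).
#' @param n_steps Number of timesteps (>= 1).
#' @param method Effective-Hamiltonian flavor, see
#'   [hamiltonian_coefficients()].
#' @param temperature Simulation temperature; defaults to `cfg$t_ref`.
#' @return The advanced `sim_state`.
#' @export
step_langevin <- function(system, state, cfg, lam = 1, n_steps,
                          method = "sst2", temperature = cfg$t_ref) {
  if (lam <= 0) stop("invalid scaling factor")
  if (n_steps < 1) stop("n_steps must be >= 1")
  co <- hamiltonian_coefficients(method, lam)

  if (!is.null(state$rng_state)) {
    assign(".Random.seed", state$rng_state, envir = globalenv())
  } else if (!is.null(cfg$seed)) {
    set.seed(cfg$seed)
  }

  dt <- cfg$timestep
  m <- cfg$mass
  n <- n_coords(system)
  a_coef <- exp(-cfg$friction * dt)
  b_coef <- sqrt((1 - a_coef^2) * temperature / m)

  x <- state$coords
  v <- state$velocities
  f <- effective_force(system, x, co)
  for (i in seq_len(n_steps)) {
    v <- v + 0.5 * dt * f / m
    x <- x + 0.5 * dt * v
    v <- a_coef * v + b_coef * stats::rnorm(n)
    x <- x + 0.5 * dt * v
    f <- effective_force(system, x, co)
    if (!all(is.finite(f))) stop("integration blow-up at step ", i)
    v <- v + 0.5 * dt * f / m
  }
  state$coords <- x
  state$velocities <- v
  state$time <- state$time + n_steps * dt
  state$rng_state <- get(".Random.seed", envir = globalenv())
  state
}

#' Closed-form log partition function of the harmonic toy system
#'
#' For an uncoupled harmonic system under the SST2-scaled Hamiltonian at
#' the reference temperature, each scalable solute coordinate contributes a
#' Gaussian integral with stiffness `lam * k_solute`:
#' \deqn{\ln Z(\lambda) = \frac{d_1}{2}\ln\frac{2\pi}{\beta_{ref}\lambda k}
#'  + \frac{d_2}{2}\ln\frac{2\pi}{\beta_{ref} k}
#'  + \frac{d_w}{2}\ln\frac{2\pi}{\beta_{ref} k_w}}
#' with `d_1`/`d_2` the scalable/unscaled solute counts. This is the oracle
#' against which estimated tempering weights are checked.
#'
#' @inheritParams step_langevin
#' @param t_ref Reference temperature, reduced units.
#' @return `ln Z(lam)`, dimensionless.
#' @export
analytic_log_partition <- function(system, lam, t_ref) {
  if (system$potential != "harmonic") stop("no closed form")
  if (system$coupling != 0) stop("no closed form")
  beta <- 1 / t_ref
  d2 <- length(system$unscaled_solute)
  d1 <- system$d_solute - d2
  (d1 / 2) * log(2 * pi / (beta * lam * system$k_solute)) +
    (d2 / 2) * log(2 * pi / (beta * system$k_solute)) +
    (system$d_solvent / 2) * log(2 * pi / (beta * system$k_solvent))
}

#' Ideal tempering weights of a harmonic toy system
#'
#' The weights that make rung occupancy exactly uniform are
#' `w_m = -(ln Z_m - ln Z_ref)`; for the fully scalable harmonic solute
#' this is `(d_solute / 2) * ln(lam_m)`.
#'
#' @param system A harmonic, uncoupled [toy_system()].
#' @param ladder A [build_ladder()] result.
#' @return Numeric vector of per-rung weights, 0 at the reference rung.
#' @export
ideal_weights <- function(system, ladder) {
  lnz <- vapply(ladder$rungs$lam, analytic_log_partition,
                numeric(1), system = system, t_ref = ladder$t_ref)
  ref <- lnz[ladder$ref_index + 1L]
  -(lnz - ref)
}
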