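# Expanded-ensemble engines: rung-move acceptance for ST/SST1/SST2, the
# pairwise REST2 swap criterion, and the two weight-estimation schemes.

#' Initialize the tempering state
#'
#' Holds the walker's current rung, the per-rung weight table (reference
#' rung pinned to 0 as the gauge choice), per-rung running sums of the four
#' decomposition energies, and visit counts.
#'
#' @param ladder A [build_ladder()] result.
#' @param start_rung 0-based starting rung; defaults to the reference rung.
#' @return An object of class `temper_state`.
#' @export
temper_state <- function(ladder, start_rung = ladder$ref_index) {
  n <- ladder$n_rungs
  structure(
    list(current_rung = as.integer(start_rung),
         weights = ladder$rungs$weight,
         sum_epp1 = numeric(n), sum_epp2 = numeric(n),
         sum_epw = numeric(n), sum_eww = numeric(n),
         visit_counts = integer(n), step = 0L,
         ref_index = ladder$ref_index),
    class = "temper_state"
  )
}

# Dimensionless "acceptance energy" u_m(X): beta_m * E(X) for plain ST,
# beta_ref * E_m^method(X) for the Hamiltonian-scaled methods. Rung moves
# satisfy exact detailed balance w.r.t. exp(w_m - u_m(X)).
acceptance_energy <- function(decomp, rung, ref, method) {
  if (method == "st") {
    rung$beta * (decomp$epp1 + decomp$epp2 + decomp$epw + decomp$eww)
  } else {
    ref$beta * scaled_energy(decomp, rung, ref, method)
  }
}

#' Log acceptance ratio of a rung move
#'
#' For the Hamiltonian-scaled methods,
#' \deqn{\Delta_{mn} = -\beta_{ref}[E_n^{method}(X) - E_m^{method}(X)] + (w_n - w_m),}
#' which for SST2 expands to
#' \eqn{(\beta_m-\beta_n)E_{pp}^{(1)} +
#' (\sqrt{\beta_{ref}\beta_m}-\sqrt{\beta_{ref}\beta_n})E_{pw} + (w_n-w_m)};
#' for plain ST, \eqn{\Delta_{mn} = (\beta_m-\beta_n)E + (w_n - w_m)}. The
#' move is accepted with probability `min(1, exp(delta))`.
#'
#' @param decomp The configuration's unscaled [energy_decomposition()].
#' @param m,n Current and proposed rung rows ([ladder_rung()]); must be
#'   equal or adjacent.
#' @param ref Reference rung row.
#' @param weights Per-rung weight vector (index order).
#' @param method One of `"st"`, `"sst1"`, `"sst2"`.
#' @return The scalar log acceptance ratio \eqn{\Delta_{mn}}.
#' @export
delta_rung <- function(decomp, m, n, ref, weights, method = "sst2") {
  if (abs(n$index - m$index) > 1) stop("illegal move")
  u_m <- acceptance_energy(decomp, m, ref, method)
  u_n <- acceptance_energy(decomp, n, ref, method)
  -(u_n - u_m) + (weights[n$index + 1L] - weights[m$index + 1L])
}

#' Attempt one Metropolis rung move
#'
#' Proposes the up or down neighbor with probability 1/2 each; at a ladder
#' end the out-of-range proposal is an automatic rejection, which keeps the
#' proposal symmetric and the Metropolis ratio weight-free. Before the
#' proposal, the current segment's energies are committed to the occupied
#' rung's running means and visit count. The proposal draw and (for
#' in-range proposals) the acceptance draw consume, in that order, from the
#' ambient seeded RNG stream.
#'
#' @param state A [temper_state()].
#' @param decomp The configuration's unscaled [energy_decomposition()].
#' @param ladder The [build_ladder()] result.
#' @param method One of `"st"`, `"sst1"`, `"sst2"`.
#' @param monitor_variant Passed to [monitor_energy()].
#' @return A list with the updated `state` and a one-row data frame
#'   `record` (from_rung, to_rung, delta, accepted, monitor, step).
#' @export
attempt_move <- function(state, decomp, ladder, method = "sst2",
                         monitor_variant = "radical") {
  from <- state$current_rung
  i <- from + 1L
  state$sum_epp1[i] <- state$sum_epp1[i] + decomp$epp1
  state$sum_epp2[i] <- state$sum_epp2[i] + decomp$epp2
  state$sum_epw[i] <- state$sum_epw[i] + decomp$epw
  state$sum_eww[i] <- state$sum_eww[i] + decomp$eww
  state$visit_counts[i] <- state$visit_counts[i] + 1L
  state$step <- state$step + 1L

  ref <- ladder$rungs[ladder$ref_index + 1L, ]
  mon <- monitor_energy(decomp, ladder$rungs[i, ], ref, monitor_variant)

  to <- from + (if (stats::runif(1) < 0.5) 1L else -1L)
  if (to < 0L || to >= ladder$n_rungs) {
    delta <- NA_real_
    accepted <- FALSE
  } else {
    delta <- delta_rung(decomp, ladder$rungs[i, ], ladder$rungs[to + 1L, ],
                        ref, state$weights, method)
    accepted <- log(stats::runif(1)) < delta
    if (accepted) state$current_rung <- to
  }
  list(state = state,
       record = data.frame(from_rung = from, to_rung = to, delta = delta,
                           accepted = accepted, monitor = mon,
                           step = state$step))
}

rung_mean_decomp <- function(state, i) {
  n <- state$visit_counts[i]
  energy_decomposition(epp1 = state$sum_epp1[i] / n,
                       epp2 = state$sum_epp2[i] / n,
                       epw = state$sum_epw[i] / n,
                       eww = state$sum_eww[i] / n)
}

# <u_b - u_a> over rung k's samples, using the stored linear running means.
mean_u_diff <- function(state, ladder, k, a, b, method) {
  md <- rung_mean_decomp(state, k)
  ref <- ladder$rungs[ladder$ref_index + 1L, ]
  acceptance_energy(md, ladder$rungs[b, ], ref, method) -
    acceptance_energy(md, ladder$rungs[a, ], ref, method)
}

#' Extend weights on the fly to unvisited neighbor rungs
#'
#' First-visit weight guess: an unvisited rung adjacent to a visited rung m
#' gets \eqn{w_{m+1} = w_m + \beta_{ref}\langle E_{m+1}^{method} -
#' E_m^{method}\rangle_m} (which reduces exactly to
#' \eqn{w_m + (\beta_{m+1}-\beta_m)\langle E\rangle_m} for plain ST).
#' Applied outward in both directions from the visited region; a rung's
#' guess is only ever written while it has no samples of its own.
#'
#' @inheritParams attempt_move
#' @return The updated `temper_state`.
#' @export
update_weights_on_the_fly <- function(state, ladder, method = "sst2") {
  if (all(state$visit_counts == 0L)) stop("insufficient statistics")
  n <- ladder$n_rungs
  for (i in seq_len(n - 1L)) {            # upward sweep
    if (state$visit_counts[i] > 0L && state$visit_counts[i + 1L] == 0L) {
      state$weights[i + 1L] <- state$weights[i] +
        mean_u_diff(state, ladder, i, i, i + 1L, method)
    }
  }
  for (i in seq(n, 2L)) {                 # downward sweep
    if (state$visit_counts[i] > 0L && state$visit_counts[i - 1L] == 0L) {
      state$weights[i - 1L] <- state$weights[i] +
        mean_u_diff(state, ladder, i, i, i - 1L, method)
    }
  }
  state
}

#' Refresh the whole weight table from averaged energies
#'
#' Symmetric-average estimator: each link gets
#' \deqn{w_{m+1}-w_m = \tfrac12\left(\langle u_{m+1}-u_m\rangle_m +
#'   \langle u_{m+1}-u_m\rangle_{m+1}\right)}
#' with \eqn{u_m = \beta_{ref} E_m^{method}} (or \eqn{\beta_m E} for ST) —
#' the balance condition that equalizes the typical forward and backward
#' log acceptance ratios across the link. Links with samples on only one
#' side fall back to the one-sided on-the-fly estimate (flagged via a
#' warning); links with no samples keep their previous difference. The
#' reference rung is re-pinned to 0.
#'
#' @inheritParams attempt_move
#' @return The updated `temper_state`.
#' @export
update_weights_averaged <- function(state, ladder, method = "sst2") {
  n <- ladder$n_rungs
  dw <- diff(state$weights)
  fallback <- FALSE
  for (i in seq_len(n - 1L)) {
    n_lo <- state$visit_counts[i]
    n_hi <- state$visit_counts[i + 1L]
    if (n_lo > 0L && n_hi > 0L) {
      dw[i] <- (mean_u_diff(state, ladder, i, i, i + 1L, method) +
                mean_u_diff(state, ladder, i + 1L, i, i + 1L, method)) / 2
    } else if (n_lo > 0L) {
      dw[i] <- mean_u_diff(state, ladder, i, i, i + 1L, method)
      fallback <- TRUE
    } else if (n_hi > 0L) {
      dw[i] <- mean_u_diff(state, ladder, i + 1L, i, i + 1L, method)
      fallback <- TRUE
    }
  }
  if (fallback) warning("averaged refresh fell back to one-sided estimates on sparsely visited links")
  w <- c(0, cumsum(dw))
  state$weights <- w - w[state$ref_index + 1L]
  state
}

#' Re-estimate the weight table from a trajectory log
#'
#' Rebuilds the per-rung running means from the recorded energies —
#' discarding an initial burn-in fraction — and applies the averaged
#' (symmetric) refresh. Used for the final refresh of adaptive runs and for
#' offline re-estimation from saved logs.
#'
#' @param log A `trajectory_log`.
#' @param burn_in_fraction Fraction of initial segments discarded
#'   (default the log's configured value).
#' @param prior_weights Weight table used for links without samples
#'   (default the log's final estimate, else zeros).
#' @return A `temper_state` with the refreshed weights.
#' @export
estimate_weights_from_log <- function(log, burn_in_fraction = NULL,
                                      prior_weights = NULL) {
  stopifnot(inherits(log, "trajectory_log"))
  records <- log$records
  if (nrow(records) == 0) stop("empty log")
  ladder <- log$header$ladder
  method <- log$header$config$method
  burn_in_fraction <- burn_in_fraction %||%
    log$header$config$schedule$burn_in_fraction
  keep <- records$step > burn_in_fraction * max(records$step)
  st <- temper_state(ladder)
  idx <- factor(records$rung_index[keep] + 1L,
                levels = seq_len(ladder$n_rungs))
  sum_by <- function(v) {
    s <- tapply(v, idx, sum)
    ifelse(is.na(s), 0, as.numeric(s))
  }
  st$sum_epp1 <- sum_by(records$epp1[keep])
  st$sum_epp2 <- sum_by(records$epp2[keep])
  st$sum_epw <- sum_by(records$epw[keep])
  st$sum_eww <- sum_by(records$eww[keep])
  st$visit_counts <- as.integer(table(idx))
  st$weights <- prior_weights %||% log$final$temper_state$weights %||%
    numeric(ladder$n_rungs)
  update_weights_averaged(st, ladder, method)
}

#' Pairwise REST2 swap criterion
#'
#' Exact log acceptance ratio for exchanging the configurations of two
#' replicas m and n running REST2-scaled Hamiltonians at the reference
#' temperature:
#' \deqn{\Delta = -\beta_{ref}[E_m(X_n) + E_n(X_m) - E_m(X_m) - E_n(X_n)].}
#'
#' @param decomp_m,decomp_n Unscaled [energy_decomposition()]s of the two
#'   replicas' configurations.
#' @param m,n Rung rows of the two replicas.
#' @param ref Reference rung row.
#' @return The scalar log acceptance ratio.
#' @export
rest2_pair_delta <- function(decomp_m, decomp_n, m, n, ref) {
  e <- function(d, r) scaled_energy(d, r, ref, "rest2")
  -ref$beta * (e(decomp_n, m) + e(decomp_m, n) -
               e(decomp_m, m) - e(decomp_n, n))
}

#' Run a tempering simulation on a toy system
#'
#' Alternates MD segments of `exchange_interval` BAOAB steps on the current
#' rung's effective Hamiltonian with Metropolis rung moves, applying the
#' configured weight-update schedule. Hamiltonian-scaled methods propagate
#' at the reference temperature; plain ST propagates the unscaled potential
#' at the current rung's temperature. One seeded RNG stream drives
#' integrator noise, proposal draws and acceptance draws, in that order
#' within each segment, so runs are fully reproducible from
#' (configuration, seed).
#'
#' @param system A [toy_system()].
#' @param ladder A [build_ladder()] result; its `t_ref` is the reduced
#'   simulation reference temperature.
#' @param cfg A [run_config()].
#' @return A `trajectory_log`: list with `header` (config echo, ladder,
#'   seed, unit system), `records` (one row per exchange attempt: step,
#'   time, rung_index, lambda, the four energies, monitor, proposed_rung,
#'   delta, accepted, order_param), `weights_history` (matrix of the weight
#'   table at each refresh), and `final` (sim state and temper state).
#' @export
run_tempering <- function(system, ladder, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  method <- cfg$method
  sched <- cfg$schedule
  n_seg <- sched$n_segments
  exch <- sched$exchange_interval
  weight_update <- sched$weight_update
  monitor_variant <- cfg$flags$monitor_variant
  set.seed(cfg$seed)

  icfg <- integrator_config(timestep = cfg$integrator$timestep,
                            friction = cfg$integrator$friction,
                            t_ref = ladder$t_ref, seed = NULL)
  state <- sim_state(system)
  tstate <- temper_state(ladder,
                         start_rung = cfg$start_rung %||% ladder$ref_index)
  tstate$weights <- cfg$initial_weights %||% tstate$weights

  cols <- c("step", "time", "rung_index", "lambda", "epp1", "epp2", "epw",
            "eww", "monitor", "proposed_rung", "delta", "accepted",
            "order_param")
  rec <- lapply(stats::setNames(cols, cols), function(.) numeric(n_seg))

  w_hist <- list(`0` = tstate$weights)
  all_visited <- all(tstate$visit_counts > 0L)

  for (s in seq_len(n_seg)) {
    rung <- ladder$rungs[tstate$current_rung + 1L, ]
    if (method == "st") {
      state <- step_langevin(system, state, icfg, lam = 1,
                             n_steps = exch, method = "st",
                             temperature = rung$temperature)
    } else {
      state <- step_langevin(system, state, icfg, lam = rung$lam,
                             n_steps = exch, method = method)
    }
    state$rng_state <- NULL   # keep one ambient stream across segments
    decomp <- decompose_energy(system, state$coords)
    mv <- attempt_move(tstate, decomp, ladder, method, monitor_variant)
    tstate <- mv$state

    rec$step[s] <- s; rec$time[s] <- state$time
    rec$rung_index[s] <- mv$record$from_rung
    rec$lambda[s] <- rung$lam
    rec$epp1[s] <- decomp$epp1; rec$epp2[s] <- decomp$epp2
    rec$epw[s] <- decomp$epw; rec$eww[s] <- decomp$eww
    rec$monitor[s] <- mv$record$monitor
    rec$proposed_rung[s] <- mv$record$to_rung
    rec$delta[s] <- mv$record$delta
    rec$accepted[s] <- mv$record$accepted
    rec$order_param[s] <- state$coords[1]

    if (weight_update != "fixed" && !all_visited) {
      old_w <- tstate$weights
      tstate <- update_weights_on_the_fly(tstate, ladder, method)
      if (any(tstate$weights != old_w)) w_hist[[as.character(s)]] <- tstate$weights
      all_visited <- all(tstate$visit_counts > 0L)
    } else if (weight_update == "averaged" &&
               s %% sched$weight_refresh_interval == 0L) {
      tstate <- update_weights_averaged(tstate, ladder, method)
      w_hist[[as.character(s)]] <- tstate$weights
    }
  }

  records <- as.data.frame(rec)
  records$accepted <- as.logical(records$accepted)

  log <- structure(
    list(header = list(config = cfg, ladder = ladder, seed = cfg$seed,
                       unit_system = "reduced",
                       version = as.character(utils::packageVersion("soltemper"))),
         records = records,
         weights_history = do.call(rbind, w_hist),
         final = list(sim_state = state, temper_state = tstate)),
    class = "trajectory_log"
  )

  # final refresh on post-burn-in samples only
  if (weight_update == "averaged" && n_seg > 0L) {
    ts2 <- estimate_weights_from_log(log)
    ts2$current_rung <- tstate$current_rung
    w_hist[["final"]] <- ts2$weights
    log$weights_history <- do.call(rbind, w_hist)
    log$final$temper_state <- ts2
    if (any(ts2$visit_counts == 0L)) {
      warning("some rungs were never visited; their weights are extrapolated")
    }
  }
  log
}

`%||%` <- function(a, b) if (is.null(a)) b else a
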