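# Post-processing: effective temperature, state classification with
# hysteresis, transition counting, stability curves, 4PL melting fit, and
# per-rung exchange diagnostics.

#' Effective solute temperature of a scaled-Hamiltonian rung
#'
#' Because the solvent stays at the reference temperature while the solute
#' Hamiltonian is scaled, the solute's effective temperature lies between
#' the nominal rung temperature and the reference, set by the balance of
#' solute-solute and solute-solvent energies:
#' \deqn{\langle\beta'_m\rangle = \beta_m\left(1 +
#'   \left(\frac{\beta_{ref}}{\beta_m}-1\right)
#'   \left\langle\frac{E_{pw}}{E_{pp}+E_{pw}}\right\rangle\right)}
#' with \eqn{E_{pp} = E_{pp}^{(1)}+E_{pp}^{(2)}}; the ratio is averaged
#' framewise (not as a ratio of averages).
#'
#' @param decomps List of per-frame [energy_decomposition()]s sampled at
#'   rung `m`, or a data frame with columns `epp1`, `epp2`, `epw`.
#' @param m,ref Rung rows ([ladder_rung()]).
#' @param k_B Boltzmann constant of the ladder's unit system (default 1).
#' @return A list of class `effective_temperature`: `rung`, `beta_eff`,
#'   `t_eff`, `ratio_mean`.
#' @export
effective_temperature <- function(decomps, m, ref, k_B = 1) {
  if (is.data.frame(decomps)) {
    epp <- decomps$epp1 + decomps$epp2
    epw <- decomps$epw
  } else {
    if (length(decomps) < 1) stop("undefined ratio: no frames")
    epp <- vapply(decomps, function(d) d$epp1 + d$epp2, numeric(1))
    epw <- vapply(decomps, function(d) d$epw, numeric(1))
  }
  denom <- epp + epw
  ok <- is.finite(denom) & denom != 0
  if (!any(ok)) stop("undefined ratio")
  ratio_mean <- mean(epw[ok] / denom[ok])
  beta_eff <- m$beta * (1 + (ref$beta / m$beta - 1) * ratio_mean)
  structure(list(rung = m$index, beta_eff = beta_eff,
                 t_eff = 1 / (k_B * beta_eff), ratio_mean = ratio_mean),
            class = "effective_temperature")
}

#' Classify frames into definite states with a hysteresis band
#'
#' Frames below `low` are folded (or bound), frames above `high` are
#' unfolded (unbound), frames inside `[low, high]` are intermediate. The
#' disjoint thresholds prevent threshold-chatter from inflating transition
#' counts. Defaults are the folding convention (0.2 / 0.25 nm); use
#' (0.5, 1.0) nm for ligand binding.
#'
#' @param values Order-parameter series (e.g. backbone RMSD, nm).
#' @param low,high Thresholds with `low < high`.
#' @param times Optional per-frame times.
#' @param rungs Optional per-frame rung indices.
#' @param labels Pair of state names, default `c("folded", "unfolded")`.
#' @return A data frame of class `state_series` with columns `time`,
#'   `value`, `state` (factor: folded/intermediate/unfolded), `rung`.
#' @export
classify_states <- function(values, low = 0.2, high = 0.25, times = NULL,
                            rungs = NULL, labels = c("folded", "unfolded")) {
  if (low >= high) stop("invalid hysteresis band: low must be < high")
  state <- ifelse(values < low, labels[1],
                  ifelse(values > high, labels[2], "intermediate"))
  out <- data.frame(
    time = times %||% seq_along(values),
    value = values,
    state = factor(state, levels = c(labels[1], "intermediate", labels[2])),
    rung = rungs %||% NA_integer_
  )
  class(out) <- c("state_series", "data.frame")
  out
}

#' Count committed transitions between the two definite states
#'
#' A two-state hysteresis automaton: intermediate frames are skipped, and a
#' transition is counted each time the last-committed definite state flips.
#' The count is invariant under time reversal of the series.
#'
#' @param series A [classify_states()] result (or a factor/character vector
#'   of states).
#' @return Integer number of committed switches.
#' @export
count_transitions <- function(series) {
  states <- if (is.data.frame(series)) series$state else series
  if (length(states) == 0) stop("no data")
  s <- as.character(states)
  definite <- s[s != "intermediate"]
  if (length(definite) < 2) return(0L)
  sum(definite[-1] != definite[-length(definite)])
}

#' Folded fraction per rung, with binomial confidence intervals
#'
#' Per rung, the fraction of definite frames in the folded state;
#' intermediate frames are excluded from both numerator and denominator
#' (the two states are defined by disjoint thresholds, the band in between
#' is unassigned). Frames can be masked out beforehand (e.g. cis-proline
#' frames via [cis_mask()]). The temperature axis uses effective
#' temperatures when supplied, raw rung temperatures otherwise.
#'
#' @param series A [classify_states()] result with per-frame rungs.
#' @param ladder The [build_ladder()] result.
#' @param effective_temps Optional numeric vector of per-rung effective
#'   temperatures (index order).
#' @param exclude Optional logical mask; `TRUE` frames are dropped.
#' @param conf Confidence level for the normal-approximation binomial CI.
#' @return Data frame with columns `rung`, `temperature`, `n`, `fraction`,
#'   `ci_lo`, `ci_hi`; rungs with no definite frames have `NA` fraction.
#' @export
folded_fraction_curve <- function(series, ladder, effective_temps = NULL,
                                  exclude = NULL, conf = 0.95) {
  stopifnot(is.data.frame(series))
  if (!is.null(exclude)) series <- series[!exclude, , drop = FALSE]
  folded_lab <- levels(series$state)[1]
  unfolded_lab <- levels(series$state)[3]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  idx <- ladder$rungs$index
  temps <- if (!is.null(effective_temps)) effective_temps else ladder$rungs$temperature
  rows <- lapply(seq_along(idx), function(i) {
    sub <- series$state[series$rung == idx[i]]
    n_f <- sum(sub == folded_lab)
    n_u <- sum(sub == unfolded_lab)
    n <- n_f + n_u
    if (n == 0) {
      data.frame(rung = idx[i], temperature = temps[i], n = 0L,
                 fraction = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
    } else {
      p <- n_f / n
      se <- sqrt(p * (1 - p) / n)
      data.frame(rung = idx[i], temperature = temps[i], n = n, fraction = p,
                 ci_lo = max(0, p - z * se), ci_hi = min(1, p + z * se))
    }
  })
  do.call(rbind, rows)
}

#' Fit a four-parameter logistic melting curve
#'
#' Least-squares fit of
#' \deqn{y = d + \frac{a - d}{1 + (x/c)^b}}
#' to a (temperature, folded fraction) table: `a` is the low-temperature
#' plateau, `d` the high-temperature plateau, `c` the inflection point
#' (the melting temperature \eqn{T_m}) and `b` the Hill slope.
#' Levenberg-Marquardt with box bounds; initialized at `a = max(y)`,
#' `d = min(y)`, `c` at the temperature closest to the half-height, and
#' `b = 10`.
#'
#' @param temperature,fraction Numeric vectors (fractions in `[0, 1]`).
#' @param weights Optional fit weights.
#' @return A list of class `melting_fit`: `a`, `d`, `c`, `b`, `covariance`
#'   (4x4), `fit` (the `nls` object), and `extrapolated` (TRUE when `c`
#'   falls outside the fitted temperature span).
#' @export
fit_melting_curve <- function(temperature, fraction, weights = NULL) {
  if (length(temperature) < 5) stop("fit failed: need at least 5 points")
  y <- fraction; x <- temperature
  if (diff(range(y)) < 0.05) stop("no sigmoid: flat data")
  a0 <- max(y); d0 <- min(y)
  c0 <- x[which.min(abs(y - (a0 + d0) / 2))]
  span <- range(x); pad <- 0.2 * diff(span)
  fit <- minpack.lm::nlsLM(
    y ~ d + (a - d) / (1 + (x / c)^b),
    start = list(a = a0, d = d0, c = c0, b = 10),
    lower = c(a = -0.2, d = -0.2, c = span[1] - pad, b = 1e-6),
    upper = c(a = 1.2, d = 1.2, c = span[2] + pad, b = Inf),
    weights = weights %||% rep(1, length(y)),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  if (!fit$convInfo$isConv) stop("fit failed: no convergence; residual SS = ",
                                 signif(sum(stats::resid(fit)^2), 4))
  p <- stats::coef(fit)
  covm <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 4, 4))
  structure(list(a = unname(p["a"]), d = unname(p["d"]), c = unname(p["c"]),
                 b = unname(p["b"]), covariance = covm, fit = fit,
                 extrapolated = p["c"] < span[1] || p["c"] > span[2]),
            class = "melting_fit")
}

#' @export
print.melting_fit <- function(x, ...) {
  se <- suppressWarnings(sqrt(diag(x$covariance)))
  cat(sprintf("4PL melting fit: Tm = %.1f K (SE %.2f), Hill slope b = %.2f\n",
              x$c, se[3], x$b))
  cat(sprintf("  plateaus a = %.3f (low T), d = %.3f (high T)%s\n", x$a, x$d,
              if (x$extrapolated) "  [Tm outside data span]" else ""))
  invisible(x)
}

#' Per-rung exchange diagnostics of a tempering run
#'
#' Summarizes a trajectory log: per-rung acceptance probability of
#' attempted moves, rung occupancy, overall acceptance, and per-rung
#' histograms of the acceptance-ratio monitor energy (whose neighboring
#' overlap diagnoses ladder adequacy).
#'
#' @param log A `trajectory_log` from [run_tempering()].
#' @param breaks Passed to [hist()] for the monitor histograms.
#' @return A list with `per_rung` (data frame: rung, attempts, in-range
#'   attempts, acceptance probability, occupancy fraction), `overall_acceptance`,
#'   and `monitor_hist` (list of per-rung histogram objects).
#' @export
rung_diagnostics <- function(log, breaks = 30) {
  rec <- log$records
  if (nrow(rec) == 0) stop("empty log")
  ladder <- log$header$ladder
  idx <- ladder$rungs$index
  in_range <- !is.na(rec$delta)
  per_rung <- do.call(rbind, lapply(idx, function(i) {
    sel <- rec$rung_index == i
    att <- sum(sel)
    att_in <- sum(sel & in_range)
    data.frame(rung = i,
               attempts = att,
               acceptance = if (att > 0) sum(rec$accepted[sel]) / att else NA_real_,
               occupancy = att / nrow(rec))
  }))
  mon <- lapply(idx, function(i) {
    v <- rec$monitor[rec$rung_index == i]
    if (length(v) > 0) graphics::hist(v, breaks = breaks, plot = FALSE) else NULL
  })
  names(mon) <- paste0("rung_", idx)
  list(per_rung = per_rung,
       overall_acceptance = mean(rec$accepted),
       monitor_hist = mon)
}
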