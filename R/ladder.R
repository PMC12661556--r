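#' Map a temperature to its Hamiltonian scaling factor
#'
#' In solute tempering, the rung at temperature \eqn{T_m} runs with the
#' solute Hamiltonian scaled by \eqn{\lambda_m = T_{ref}/T_m = \beta_m/\beta_{ref}},
#' so that \eqn{\lambda = 1} is the unmodified physical system and hotter
#' rungs have weaker solute interactions.
#'
#' @param t Temperature(s) in kelvin (or reduced temperature units).
#' @param t_ref Reference temperature in the same units.
#' @return `t_ref / t`, dimensionless.
#' @examples
#' lambda_of_temperature(540, 300) # 0.56 at two decimals
#' @export
lambda_of_temperature <- function(t, t_ref) {
  if (any(t <= 0) || t_ref <= 0) stop("invalid temperature")
  t_ref / t
}

#' Choose the number of ladder intervals below the reference temperature
#'
#' When the reference temperature sits strictly inside `[t_min, t_max]`, the
#' ladder is built from two geometric segments sharing the reference rung.
#' This heuristic picks the split that makes the per-interval geometric
#' ratios of the two segments as equal as possible (on a log scale), i.e.
#' the split that keeps rung-to-rung temperature jumps uniform across the
#' whole ladder. Ties break toward fewer rungs below the reference.
#'
#' @param t_min,t_max,t_ref Ladder bounds and reference temperature (K).
#' @param n_rungs Total number of rungs (>= 2).
#' @return Integer number of geometric intervals between `t_min` and `t_ref`
#'   (0 when `t_ref == t_min`).
#' @seealso [build_ladder()]
#' @export
choose_split <- function(t_min, t_max, t_ref, n_rungs) {
  check_ladder_bounds(t_min, t_max, t_ref, n_rungs)
  if (t_ref == t_min) return(0L)
  if (t_ref == t_max) return(n_rungs - 1L)
  candidates <- seq_len(n_rungs - 2L)  # need >= 1 interval on each side
  log_r_below <- log(t_ref / t_min) / candidates
  log_r_above <- log(t_max / t_ref) / (n_rungs - 1L - candidates)
  candidates[which.min(abs(log_r_below - log_r_above))]
}

check_ladder_bounds <- function(t_min, t_max, t_ref, n_rungs) {
  if (!(t_min > 0 && t_min <= t_ref && t_ref <= t_max)) {
    stop("invalid ladder bounds: need 0 < t_min <= t_ref <= t_max")
  }
  if (n_rungs < 2) stop("invalid ladder bounds: n_rungs must be >= 2")
  invisible(TRUE)
}

#' Build an exponentially spaced temperature ladder
#'
#' Rung temperatures are geometric within each segment:
#' \eqn{T_k = T_{lo} (T_{hi}/T_{lo})^{k/(m-1)}} with \eqn{m} points per
#' segment. When the reference temperature differs from `t_min`, the same
#' formula is applied separately between `t_min` and `t_ref` and between
#' `t_ref` and `t_max`, with the reference rung shared, so the reference is
#' always one of the rungs and `lam == 1` exactly there.
#'
#' @inheritParams choose_split
#' @param n_below_ref Number of geometric intervals between `t_min` and
#'   `t_ref`. When `NULL`, chosen by [choose_split()]. Must be 0 (or absent)
#'   when `t_ref == t_min`.
#' @param k_B Boltzmann constant in the energy unit system of the attached
#'   energy model. Defaults to 1 (reduced units); the unit system is carried
#'   by the ladder, never implicit downstream.
#' @return An object of class `ladder_spec`: a list with the construction
#'   parameters and a data frame `rungs` with columns `index` (0-based),
#'   `temperature`, `beta` (= 1/(k_B T)), `lam` (= t_ref/T) and `weight`
#'   (initialized to 0; the reference rung's weight is the pinned gauge).
#' @examples
#' lad <- build_ladder(280, 540, 300, 10, n_below_ref = 1)
#' round(lad$rungs$temperature, 1)
#' round(lad$rungs$lam, 2)
#' @export
build_ladder <- function(t_min, t_max, t_ref, n_rungs, n_below_ref = NULL,
                         k_B = 1) {
  check_ladder_bounds(t_min, t_max, t_ref, n_rungs)
  n_rungs <- as.integer(n_rungs)
  if (is.null(n_below_ref)) {
    n_below_ref <- choose_split(t_min, t_max, t_ref, n_rungs)
  }
  n_below_ref <- as.integer(n_below_ref)
  if (n_below_ref < 0 || n_below_ref > n_rungs - 1L) {
    stop("rung budget exhausted: n_below_ref must lie in [0, n_rungs - 1]")
  }
  if (t_ref == t_min && n_below_ref != 0L) {
    stop("invalid ladder bounds: n_below_ref must be 0 when t_ref == t_min")
  }
  if (t_ref > t_min && n_below_ref == 0L) {
    stop("rung budget exhausted: need at least one interval below t_ref")
  }
  n_above <- n_rungs - 1L - n_below_ref
  if (t_ref < t_max && n_above == 0L) {
    stop("rung budget exhausted: need at least one interval above t_ref")
  }

  geom_segment <- function(lo, hi, n_intervals) {
    if (n_intervals == 0L) return(lo)
    lo * (hi / lo)^(seq(0L, n_intervals) / n_intervals)
  }
  temps_below <- geom_segment(t_min, t_ref, n_below_ref)
  temps_above <- geom_segment(t_ref, t_max, n_above)
  temperature <- c(temps_below, temps_above[-1L])
  # pin the shared rung exactly
  temperature[n_below_ref + 1L] <- t_ref

  rungs <- data.frame(
    index = seq_len(n_rungs) - 1L,
    temperature = temperature,
    beta = 1 / (k_B * temperature),
    lam = t_ref / temperature,
    weight = 0
  )
  structure(
    list(t_min = t_min, t_max = t_max, t_ref = t_ref,
         n_rungs = n_rungs, n_below_ref = n_below_ref,
         k_B = k_B, ref_index = n_below_ref,
         rungs = rungs),
    class = "ladder_spec"
  )
}

#' @export
print.ladder_spec <- function(x, ...) {
  cat(sprintf(
    "Temperature ladder: %d rungs, T in [%g, %g] K, T_ref = %g K (rung %d), k_B = %g\n",
    x$n_rungs, x$t_min, x$t_max, x$t_ref, x$ref_index, x$k_B))
  tab <- data.frame(
    index = x$rungs$index,
    temperature = round(x$rungs$temperature, 1),
    lambda = round(x$rungs$lam, 2),
    weight = signif(x$rungs$weight, 6)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Extract one rung of a ladder
#'
#' @param ladder A `ladder_spec`.
#' @param index 0-based rung index.
#' @return A one-row data frame (a `Rung`): `index`, `temperature`, `beta`,
#'   `lam`, `weight`.
#' @export
ladder_rung <- function(ladder, index) {
  stopifnot(inherits(ladder, "ladder_spec"))
  i <- match(as.integer(index), ladder$rungs$index)
  if (is.na(i)) stop("no such rung: ", index)
  ladder$rungs[i, , drop = FALSE]
}

#' @rdname ladder_rung
#' @export
reference_rung <- function(ladder) ladder_rung(ladder, ladder$ref_index)
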