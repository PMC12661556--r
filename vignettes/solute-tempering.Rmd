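---
title: "Solute tempering in an expanded ensemble: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solute tempering in an expanded ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soltemper)
```

## The expanded ensemble

All engines in `soltemper` sample one joint chain over (configuration,
rung). The target distribution is

$$\pi(m, X) \propto \exp\big(w_m - u_m(X)\big),$$

where the dimensionless "acceptance energy" $u_m$ depends on the method:

* **ST** — the plain potential at the rung's own temperature,
  $u_m = \beta_m E(X)$. The trajectory is propagated at $T_m$.
* **SST1** — the REST-scaled Hamiltonian
  ($E_{pp} + \tfrac{\beta_{ref}+\beta_m}{2\beta_m}E_{pw} +
  \tfrac{\beta_{ref}}{\beta_m}E_{ww}$) sampled at the reference
  temperature, $u_m = \beta_{ref} E^{rest}_m(X)$.
* **SST2** — the REST2-style Hamiltonian
  $E_m = \lambda_m E_{pp}^{(1)} + E_{pp}^{(2)} + \sqrt{\lambda_m}\,E_{pw} +
  E_{ww}$ sampled at $T_{ref}$, $u_m = \beta_{ref} E_m(X)$, with
  $\lambda_m = \beta_m/\beta_{ref}$.

Rung moves propose a neighbor with probability $\tfrac12$ each (the
out-of-range proposal at a ladder end is an automatic rejection, keeping
the proposal symmetric) and accept with probability
$\min(1, e^{\Delta})$, $\Delta = -(u_n - u_m) + (w_n - w_m)$. We derive
every acceptance rule from this detailed-balance form rather than from
per-method closed forms; the algebraic identity of the two routes is
asserted in the test suite to $10^{-12}$ across randomized energy
decompositions, and the stationary distribution of the combined kernel is
checked against the leading eigenvector of an exactly enumerated
transition matrix on a 2-rung × 3-configuration chain.

A note on coefficients: the solute–solvent term carries $\sqrt{\lambda}$,
the unique choice consistent with scaling solute charges by
$\sqrt{\lambda}$ (a solute–solvent Coulomb pair then has exactly one
scaled charge). The same consistency argument fixes the acceptance-ratio
monitor as $E_{pp} + \tfrac12\sqrt{\beta_{ref}/\beta_m}\,E_{pw}$; the
variant with a plain ratio coefficient is available behind
`monitor_variant = "printed"` for comparison, but the radical form is the
default because it is the one the scaled Hamiltonian implies.

## Two equivalent scaling routes

SST2 can be realized either by evaluating the scaled Hamiltonian on an
unscaled energy decomposition, or by scaling force-field parameters:
solute LJ $\epsilon$ and selected proper-torsion constants by $\lambda$,
solute charges by $\sqrt{\lambda}$. With a geometric-mean $\epsilon$
combination rule the pair energies pick up factors $\lambda$
(solute–solute) and $\sqrt{\lambda}$ (solute–solvent) exactly, so the two
routes coincide. This is the central correctness property of the scaling
rules, and the suite asserts it to $10^{-10}$ relative on a randomized
LJ + Coulomb + torsion system. The geometric-mean rule is therefore a
documented constraint on any adapter that maps a real force field onto
this machinery; Lorentz–Berthelot $\sigma$ mixing is unaffected because
$\sigma$ is never scaled.

The energy decomposition itself follows an operational contract: the
solute intramolecular energy is what a solute-only copy of the system
reports, the solvent energy what a solvent-only copy reports, and the
solute–solvent interaction is the remainder of the total. The toy systems
implement this contract literally, so adapter implementations have an
unambiguous reference behavior.

Proline ω dihedrals deserve a special rule: scaling down their barrier at
hot rungs promotes *cis* states that can trap a peptide in non-native
conformations for long stretches. `partition_torsions()` therefore moves
every proper torsion whose middle bond is C(i−1)–N(i) of a proline into
the unscaled class $E_{pp}^{(2)}$ when `exclude_omega` is set; multiplicity
copies sharing that bond are caught by the same per-term test.

## Weight estimation

Weights are free-energy offsets; when exact
($w_m = -\ln Z_m + \text{const}$), rung occupancy is uniform. Two
estimators are provided:

* **On the fly** — an unvisited neighbor of a visited rung $m$ gets
  $w_{m\pm1} = w_m + \langle u_{m\pm1} - u_m\rangle_m$, a first-order
  (rectangle-rule) guess good enough to let the walker climb. It reduces
  to $w_{m+1} = w_m + (\beta_{m+1}-\beta_m)\langle E\rangle_m$ for ST.
* **Averaged** — each ladder link is refreshed with the symmetric average
  $\tfrac12(\langle u_{m+1}-u_m\rangle_m + \langle u_{m+1}-u_m\rangle_{m+1})$,
  the condition that equalizes the typical forward and backward log
  acceptance ratios across the link (a trapezoid rule in $\ln Z$). On a
  harmonic solute, fed exact means, it reproduces
  $(d/2)\ln(\beta_m/\beta_{ref})$ up to the trapezoid discretization
  error, which shrinks with rung spacing.

The default schedule uses on-the-fly extension until every rung has
samples, then periodic averaged refreshes, then one final refresh over
post-burn-in samples only. Running means are cumulative with counts, not
exponentially weighted: the estimators' convergence analysis assumes
plain averages, and reproducibility is simpler to reason about. The
burn-in fraction defaults to 10% of segments. How often production runs
should refresh is genuinely open — it trades weight accuracy against
stationarity of the sampled ensemble — so the refresh interval is plain
configuration, and weights can be frozen (`weight_update = "fixed"`) for
production.

## The toy systems and what they do (and do not) show

The built-in systems couple a solute of $d_s$ coordinates (harmonic, or a
quartic double well on the first coordinate) to a harmonic solvent bath
through a bilinear term, in reduced units ($k_B = 1$, unit masses).
They are chosen so that every estimator has a closed-form oracle: the
harmonic partition function gives exact weights
($w_m = (d_1/2)\ln\lambda_m$ for a fully scalable solute), equipartition
gives exact per-rung energy means, and the double-well coordinate serves
as an RMSD-like order parameter with a tunable barrier.

Dynamics use the BAOAB Langevin splitting — chosen for its accurate
configurational averages at finite timestep — with defaults of 0.01
reduced time units and friction 1 (the low-friction regime that favors
fast conformational diffusion in single-trajectory tempering; tests use
0.05 with the soft harmonic potentials, where the stability limit is
$\omega\,\Delta t \ll 2$). One seeded RNG stream drives integrator noise,
proposal draws and acceptance draws in a documented order, so every run
is reproducible from (config, seed).

Passing these checks demonstrates that the machinery — ladders,
acceptance, weight estimation, diagnostics — is exact in the
statistical-mechanics sense. It does not demonstrate force-field realism:
the toys have no explicit water, no long-range electrostatics (a
background-charge-corrected Ewald treatment is an adapter-level
requirement for charged solutes), no constraints or barostat, and
energies that are cheap and smooth. Claims about folding kinetics or
melting temperatures of real peptides are outside what the toy scale can
support.

## Problem sizes and statistical conventions

The suite runs everything at desk scale, as the package's own test
convention: weight recovery uses the 10-coordinate harmonic solute on the
10-rung reference ladder with 12 000 estimation segments of 10 steps
(timestep 0.05), followed by 20 000 fixed-weight production segments;
equipartition and distribution checks use $10^5$-step seeded runs.
Occupancy uniformity is tested with a χ² statistic on segments thinned at
the square of the ladder size — rung-walk samples are autocorrelated with
a relaxation time of order $n_{rungs}^2$ attempts, and the multinomial χ²
assumes independent draws, so thinning beyond that time is required for
the test to be calibrated.

Other numerical conventions:

* **Ladders** are geometric within each segment, with the reference rung
  pinned exactly and shared between segments. When the split is not
  given, `choose_split()` equalizes the per-interval geometric ratios of
  the two segments on a log scale (ties toward fewer rungs below the
  reference); this single heuristic reproduces all three reference
  ladders shipped in the tests. Temperatures are kept at full precision
  internally; printing rounds to 0.1 K and λ to two decimals.
* **4PL melting fits** use Levenberg–Marquardt with box bounds
  ($a, d \in [-0.2, 1.2]$, $b > 0$, $c$ within the data span ± 20%) and
  initialization $a = \max y$, $d = \min y$, $c$ at the half-height
  point, $b = 10$. Data whose range is below 0.05 are rejected as having
  no sigmoid rather than returning an unstable fit.
* **State classification** uses disjoint thresholds (folded < 0.2 nm,
  unfolded > 0.25 nm; bound < 0.5 nm, unbound > 1.0 nm). Frames inside
  the band are excluded from folded-fraction numerators and denominators:
  the two states are defined by disjoint cutoffs and the band is
  unassigned, so counting it either way would bias fractions. Transition
  counting runs a two-state hysteresis automaton on raw per-frame states;
  any smoothing is display-only and never enters counts. The *cis*
  threshold for ω angles is |ω| < 90°, the symmetric separatrix between
  the two planar states.
* **Effective temperatures** average the ratio
  $E_{pw}/(E_{pp}+E_{pw})$ framewise, not as a ratio of averages, and
  frames with a vanishing denominator are guarded out.
* **RMSD** uses Kabsch superposition; the ligand-in-receptor mode
  superposes on the receptor selection and evaluates the ligand RMSD
  without refitting, so ligand displacement within the binding site is
  preserved. Transition counts can be normalized per unit of total
  simulated time or per unit of reference-rung time; both are reported
  because the convention is ambiguous in common usage.

## Known limitations

* The engines drive only the built-in toy potentials; coupling to a real
  MD engine is an adapter concern, with the REST2 pairwise criterion
  (`rest2_pair_delta`) provided as an oracle for such adapters.
* SST1 here is the REST Hamiltonian inside the same reference-temperature
  expanded ensemble as SST2 — internally consistent and exactly balanced,
  but not a replica-exchange reimplementation of historical REST.
* Weight refinement beyond the averaged estimator (e.g. WHAM-style
  reweighting across rungs) is not implemented.
* The number of rungs is an input; no automatic sizing from a target
  acceptance probability is attempted.
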