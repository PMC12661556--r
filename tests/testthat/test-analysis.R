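test_that("effective temperature reproduces its limiting and hand-computed cases", {
  ref <- fake_rung(1, t_ref = 300)
  hot <- fake_rung(300 / 540, t_ref = 300, index = 9L)

  # E_pw = 0 every frame: the solute feels the nominal rung temperature
  d0 <- data.frame(epp1 = c(10, 12), epp2 = 0, epw = 0)
  expect_equal(effective_temperature(d0, hot, ref)$t_eff, 540)
  # reference rung: t_eff = t_ref regardless of the ratio
  d1 <- data.frame(epp1 = 10, epp2 = 0, epw = -5)
  expect_equal(effective_temperature(d1, ref, ref)$t_eff, 300)
  # mean ratio 0.6 with T_m = 540: beta' = beta_m (1 + 0.8 * 0.6)
  d2 <- data.frame(epp1 = 4, epp2 = 0, epw = 6)  # ratio 6/10 framewise
  r2 <- effective_temperature(d2, hot, ref)
  expect_equal(r2$ratio_mean, 0.6)
  expect_equal(r2$t_eff, 540 / 1.48, tolerance = 1e-12)
  # ratio averaged framewise, not ratio of averages
  d3 <- data.frame(epp1 = c(2, 50), epp2 = 0, epw = c(8, 50))
  expect_equal(effective_temperature(d3, hot, ref)$ratio_mean,
               mean(c(0.8, 0.5)))
  # in-range property
  expect_gte(r2$t_eff, 300); expect_lte(r2$t_eff, 540)
  expect_error(effective_temperature(data.frame(epp1 = 1, epp2 = -1, epw = 0),
                                     hot, ref), "undefined ratio")
})

test_that("state classification applies the hysteresis band", {
  s <- classify_states(c(0.1, 0.22, 0.3), low = 0.2, high = 0.25)
  expect_equal(as.character(s$state), c("folded", "intermediate", "unfolded"))
  s2 <- classify_states(c(0.21, 0.22, 0.24), low = 0.2, high = 0.25)
  expect_true(all(s2$state == "intermediate"))
  # binding convention: 0.44 nm is bound under the (0.5, 1.0) thresholds
  b <- classify_states(c(0.44, 1.2), low = 0.5, high = 1.0,
                       labels = c("bound", "unbound"))
  expect_equal(as.character(b$state), c("bound", "unbound"))
  expect_error(classify_states(1, low = 0.3, high = 0.2),
               "invalid hysteresis band")
})

test_that("transition counting is a hysteresis automaton, invariant to time reversal", {
  s <- factor(c("folded", "intermediate", "unfolded", "intermediate", "folded"),
              levels = c("folded", "intermediate", "unfolded"))
  expect_equal(count_transitions(s), 2L)
  expect_equal(count_transitions(rev(s)), 2L)
  expect_equal(count_transitions(factor("folded", levels = levels(s))), 0L)
  # a series that never leaves the band after an initial folded state
  s2 <- factor(c("folded", rep("intermediate", 10)), levels = levels(s))
  expect_equal(count_transitions(s2), 0L)
  expect_error(count_transitions(character(0)), "no data")

  # synthetic telegraph signal with a known number of committed switches,
  # plus band noise that never crosses the far threshold spuriously
  set.seed(42)
  k <- 17
  levels_tele <- rep(c(0.1, 0.4), length.out = k + 1)  # k switches
  values <- unlist(lapply(levels_tele, function(v) {
    v + stats::runif(60, -0.04, 0.04)  # stays on its own side of the band
  }))
  series <- classify_states(values, low = 0.2, high = 0.25)
  expect_equal(count_transitions(series), k)
  expect_equal(count_transitions(series[rev(seq_len(nrow(series))), ]), k)
})

test_that("folded fraction per rung recovers known probabilities and excludes masked frames", {
  lad <- build_ladder(280, 540, 300, 5, n_below_ref = 1)
  # all folded
  s_all <- classify_states(rep(0.1, 500), rungs = rep(0:4, each = 100))
  curve <- folded_fraction_curve(s_all, lad)
  expect_true(all(curve$fraction == 1))
  expect_true(all(curve$fraction >= 0 & curve$fraction <= 1))

  # per-rung folded probability recovered within 3 binomial SE;
  # intermediate frames excluded from numerator and denominator
  set.seed(9)
  p_m <- c(0.95, 0.8, 0.5, 0.2, 0.05)
  n_per <- 400
  vals <- unlist(lapply(p_m, function(p) {
    v <- ifelse(stats::runif(n_per) < p, 0.1, 0.3)
    v[sample(n_per, 40)] <- 0.22  # intermediates sprinkled in
    v
  }))
  s <- classify_states(vals, rungs = rep(0:4, each = n_per))
  curve <- folded_fraction_curve(s, lad)
  for (i in seq_len(5)) {
    se <- sqrt(p_m[i] * (1 - p_m[i]) / curve$n[i])
    expect_lt(abs(curve$fraction[i] - p_m[i]), 3 * se + 1e-9)
  }

  # cis-masked frames are excluded before fractions
  mask <- rep(FALSE, nrow(s)); mask[s$rung == 0] <- TRUE
  curve_m <- folded_fraction_curve(s, lad, exclude = mask)
  expect_true(is.na(curve_m$fraction[1]))
  expect_equal(curve_m$n[1], 0L)

  # effective temperatures replace the raw axis when provided
  eff <- c(280, 300, 310, 330, 360)
  expect_equal(folded_fraction_curve(s, lad, effective_temps = eff)$temperature,
               eff)
})

test_that("the 4PL fit recovers noiseless and noisy melting curves", {
  x <- seq(280, 400, by = 5)
  y <- four_pl(x, a = 1, d = 0, c = 343, b = 10)
  fit <- fit_melting_curve(x, y)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$d, 0, tolerance = 1e-6)
  expect_equal(fit$c, 343, tolerance = 1e-6)
  expect_equal(fit$b, 10, tolerance = 1e-6)
  expect_false(fit$extrapolated)
  expect_gte(fit$a, fit$d)  # fold-curve orientation

  set.seed(4)
  y_noisy <- y + stats::rnorm(length(x), sd = 0.02)
  fit_n <- fit_melting_curve(x, y_noisy)
  ci <- fit_n$c + c(-1, 1) * 1.96 * sqrt(fit_n$covariance[3, 3])
  expect_gte(343, ci[1]); expect_lte(343, ci[2])

  expect_error(fit_melting_curve(x, rep(0.5, length(x))), "no sigmoid")
  expect_error(fit_melting_curve(c(300, 350), c(1, 0)), "fit failed")
})

test_that("dihedral angles match planar limits and an independent construction", {
  # planar trans: zig-zag in the xy plane
  expect_equal(omega_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180)
  # planar cis: both ends on the same side
  expect_equal(omega_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               0)
  # non-planar case cross-checked against the atan2-free vector construction
  p <- list(c(0.3, 1.2, -0.5), c(0, 0, 0), c(1.4, 0.2, 0.1), c(1.9, -0.8, 1.3))
  ref_dihedral <- function(p1, p2, p3, p4) {
    cross <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                              a[1]*b[2]-a[2]*b[1])
    n1 <- cross(p2 - p1, p3 - p2); n2 <- cross(p3 - p2, p4 - p3)
    ang <- acos(sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))) * 180 / pi
    if (sum(cross(n1, n2) * (p3 - p2)) < 0) ang <- -ang
    ang
  }
  expect_equal(omega_angle(p[[1]], p[[2]], p[[3]], p[[4]]),
               ref_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
               tolerance = 1e-9)
  expect_error(omega_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "undefined dihedral")
})

test_that("cis classification uses the symmetric 90-degree separatrix", {
  expect_false(cis_mask(180))
  expect_true(cis_mask(0))
  expect_false(cis_mask(-170))
  expect_equal(cis_mask(c(10, -80, 95, 179)), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("backbone RMSD removes rigid motion and honors the fixed-superposition ligand mode", {
  set.seed(12)
  ref <- matrix(rnorm(30), ncol = 3)
  expect_equal(backbone_rmsd(ref, ref), 0, tolerance = 1e-12)

  # proper rigid motion: rotation about an arbitrary axis + translation
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ref %*% rot + matrix(c(1, -2, 3), nrow(ref), 3, byrow = TRUE)
  expect_lt(backbone_rmsd(moved, ref), 1e-9)

  # deformed frame: agreement with an independent Kabsch implementation
  deformed <- ref + 0.1 * matrix(rnorm(30), ncol = 3)
  got <- backbone_rmsd(deformed, ref)
  if (requireNamespace("bio3d", quietly = TRUE)) {
    oracle <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(deformed)),
                          fit = TRUE)
    expect_equal(got, oracle, tolerance = 1e-5)
  }
  # 3-point toy with a closed-form optimum: two point sets differing by a
  # pure z-offset pattern that no rigid motion can remove entirely
  a <- matrix(c(-1, 0, 0, 1, 0, 0, 0, 0, 0), ncol = 3, byrow = TRUE)
  b <- a; b[3, 3] <- 0.3
  # optimal superposition leaves a residual computed by brute force below
  brute <- optim(par = rep(0, 6), function(p) {
    r1 <- p[1]; r2 <- p[2]; r3 <- p[3]
    rx <- matrix(c(1,0,0, 0,cos(r1),-sin(r1), 0,sin(r1),cos(r1)), 3, 3, byrow = TRUE)
    ry <- matrix(c(cos(r2),0,sin(r2), 0,1,0, -sin(r2),0,cos(r2)), 3, 3, byrow = TRUE)
    rz <- matrix(c(cos(r3),-sin(r3),0, sin(r3),cos(r3),0, 0,0,1), 3, 3, byrow = TRUE)
    m <- b %*% (rx %*% ry %*% rz) + matrix(p[4:6], 3, 3, byrow = TRUE)
    sqrt(mean(rowSums((m - a)^2)))
  }, method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(backbone_rmsd(b, a), brute$value, tolerance = 1e-5)

  # ligand-in-receptor: superpose on the "receptor", measure the "ligand"
  # without refitting, so a pure ligand displacement survives intact
  lig <- 9:10
  rec <- 1:8
  disp <- ref
  disp[lig, 1] <- disp[lig, 1] + 2
  expect_equal(backbone_rmsd(disp, ref, fit_sel = rec, rmsd_sel = lig), 2,
               tolerance = 1e-9)
  expect_error(backbone_rmsd(ref[1:5, ], ref), "selection mismatch")
})

test_that("rung diagnostics summarize acceptance, occupancy and monitor overlap", {
  cfg <- run_config(
    method = "sst2", seed = 13,
    ladder = list(t_min = 280, t_max = 540, t_ref = 300, n_rungs = 4L,
                  n_below_ref = 1L),
    integrator = list(timestep = 0.05, friction = 1.0),
    schedule = list(exchange_interval = 10L, n_segments = 3000L,
                    weight_update = "averaged", weight_refresh_interval = 500L),
    system = list(d_solute = 6L)
  )
  log <- run_from_config(cfg)
  diag <- rung_diagnostics(log)
  expect_equal(sum(diag$per_rung$occupancy), 1)
  expect_true(all(diag$per_rung$acceptance >= 0 & diag$per_rung$acceptance <= 1,
                  na.rm = TRUE))
  expect_gt(diag$overall_acceptance, 0)
  # neighboring monitor-energy histograms share support (ladder adequacy)
  h1 <- diag$monitor_hist$rung_0; h2 <- diag$monitor_hist$rung_1
  expect_true(min(h2$breaks) < max(h1$breaks))
  expect_error(rung_diagnostics(list(records = data.frame(),
                                     header = log$header)), "empty log")
})
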