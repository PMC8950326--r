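test_that("deterministic propagator reproduces its analytic limits", {
  # gamma dt -> 0: x advances by v0 dt (Taylor limit of the kernel)
  p <- langevin_params(gamma_damp = 1e-8, dt = 0.1, noise_on = FALSE)
  tr <- ou_single_trajectory(1, 1, p, x0 = 2, v0 = 3)
  expect_equal(tr$x, 2 + 3 * 0.1, tolerance = 1e-8)
  # constant force, long time: terminal velocity f/(M gamma)
  p2 <- langevin_params(gamma_damp = 2, mass = 0.5, dt = 0.05,
                        noise_on = FALSE)
  tr2 <- ou_single_trajectory(1, 2000, p2, f_const = 3)
  expect_equal(tr2$v, 3 / (0.5 * 2), tolerance = 1e-10)
  # gamma = 0: ballistic with constant acceleration
  p0 <- langevin_params(gamma_damp = 0, dt = 0.1, noise_on = FALSE)
  tr0 <- ou_single_trajectory(1, 1, p0, f_const = 2, x0 = 1, v0 = 1)
  expect_equal(tr0$x, 1 + 1 * 0.1 + 0.5 * 2 * 0.01)
  expect_equal(tr0$v, 1 + 2 * 0.1)
})

test_that("exponential kernel composes exactly across step subdivision", {
  # one step of size dt equals two steps of size dt/2 (noise off, const f)
  one <- ou_single_trajectory(1, 1,
    langevin_params(gamma_damp = 0.7, dt = 0.1, noise_on = FALSE),
    f_const = 1.3, x0 = 0.5, v0 = -0.2)
  two <- ou_single_trajectory(1, 2,
    langevin_params(gamma_damp = 0.7, dt = 0.05, noise_on = FALSE),
    f_const = 1.3, x0 = 0.5, v0 = -0.2)
  expect_identical(round(one$x - two$x, 14), 0)
  expect_identical(round(one$v - two$v, 14), 0)
})

test_that("thermal statistics: equipartition, mobility, well variance", {
  n <- 3e4
  p <- langevin_params(gamma_damp = 1, kT = 1.5, mass = 2, dt = 0.02)
  tr <- ou_single_trajectory(n, 100, p, f_const = 2, seed = 11)
  se_var <- (1.5 / 2) * sqrt(2 / n)
  expect_lt(abs(var(tr$v) - 1.5 / 2), 3.5 * se_var)   # var(v) = kT/M
  se_mu <- sd(tr$v) / sqrt(n / 3)                     # mild autocorrelation
  expect_lt(abs(mean(tr$v) - 2 / (2 * 1)), 3 * se_mu) # <v> = f/(M gamma)
  # harmonic well: var(x) = kT/k (small dt keeps the splitting bias small)
  pw <- langevin_params(gamma_damp = 2, dt = 1e-3)
  trw <- ou_single_trajectory(n, 1000, pw, k_spring = 4, seed = 12)
  expect_lt(abs(var(trw$x) - 0.25), 3.5 * 0.25 * sqrt(2 / n))
})

test_that("translocation events are reproducible and physically sensible", {
  p <- langevin_params(dt = 0.02)
  poly <- bead_spring_polymer(10)
  pore <- membrane_pore()
  fld <- driving_field("end_force", end_force_f = 5)
  e1 <- run_translocation(poly, pore, fld, p, max_time = 1e4, seed = 42)
  e2 <- run_translocation(poly, pore, fld, p, max_time = 1e4, seed = 42)
  expect_true(e1$success)
  expect_identical(e1$tau, e2$tau)
  expect_identical(e1$n_steps, e2$n_steps)
  expect_gt(e1$tau, 0)
  e3 <- run_translocation(poly, pore, fld, p, max_time = 1e4, seed = 43)
  expect_false(identical(e1$tau, e3$tau))
  # failed events record the timeout
  weak <- run_translocation(poly, pore,
                            driving_field("end_force", end_force_f = 0.01),
                            langevin_params(dt = 0.02, noise_on = FALSE),
                            max_time = 10, seed = 1)
  expect_false(weak$success)
  expect_equal(weak$timeout, 10)
  expect_true(is.na(weak$tau))
})

test_that("ballistic single bead crosses the pore in distance/velocity time", {
  # overdamped bead, noise off: instant terminal velocity v = f/(M gamma)
  gam <- 100; f <- 500; v <- f / gam
  p <- langevin_params(gamma_damp = gam, dt = 1e-4, noise_on = FALSE)
  pore <- membrane_pore(wall_thickness = 0.5)
  ev <- run_translocation(bead_spring_polymer(1), pore,
                          driving_field("end_force", end_force_f = f), p,
                          max_time = 100, seed = 5)
  # bead starts at the cis face; crossing is the pore midpoint
  expect_equal(ev$tau, (0.5 / 2) / v, tolerance = 0.1)
})

test_that("success fraction grows with field strength", {
  p <- langevin_params(dt = 0.02)
  poly <- bead_spring_polymer(8)
  pore <- membrane_pore()
  frac <- vapply(c(2e5, 1e6, 5e6), function(E) {
    ok <- vapply(1:100, function(i) {
      run_translocation(poly, pore, driving_field("electric_uniform", E = E),
                        p, max_time = 25, seed = 9000 + i)$success
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[3], frac[1])
})

test_that("the membrane expels beads placed inside the wall", {
  pore <- membrane_pore(wall_position = 0, wall_thickness = 1,
                        pore_radius = 1)
  pos <- matrix(c(0.5, 3), 2, 1)  # inside the slab, far outside the opening
  poly <- bead_spring_polymer(1, positions = pos)
  p <- langevin_params(dt = 0.01, noise_on = FALSE)
  out <- langevin_step(poly, p, pore = pore, n_steps = 500)
  x <- out$positions[1, 1]
  expect_true(x <= 0 || x >= 1)
  expect_error(
    run_translocation(bead_spring_polymer(2, bond_length = 3),
                      membrane_pore(pore_radius = 1),
                      driving_field("none"), p),
    "thread")
})

test_that("stokes drift velocity follows the Coulomb/Stokes balance", {
  expect_equal(stokes_drift_velocity(1, 0, 1e-3, 1e-9), 0)
  expect_equal(stokes_drift_velocity(2, 3, 1e-3, 1e-9),
               2 * stokes_drift_velocity(1, 3, 1e-3, 1e-9))
  expect_equal(stokes_drift_velocity(1.6e-19, 1e6, 1e-3, 1e-9),
               8.49e-3, tolerance = 1e-3)
  expect_error(stokes_drift_velocity(1, 1, 0, 1), "eta")
  # SI -> reduced mapping places 1e6 V/m near unit reduced force
  expect_equal(efield_reduced_force(1e6), 0.98, tolerance = 0.01)
})

test_that("escape-time surface reports per-cell statistics", {
  surf <- escape_time_surface(E_values = 4e6, N_values = 6, replicates = 1,
                              seed = 3)
  expect_equal(nrow(surf), 1)
  ev <- run_translocation(bead_spring_polymer(6), membrane_pore(),
                          driving_field("electric_uniform", E = 4e6),
                          langevin_params(dt = 0.02), max_time = 2e4,
                          seed = 3 * 1e6 + 0 * 1e4 + 1)
  expect_equal(surf$mean_tau, ev$tau)  # one cell, one replicate
  expect_error(escape_time_surface(numeric(0), 5), "non-empty")
})

test_that("histogram statistics refuse underpowered runs", {
  expect_error(
    translocation_histogram(bead_spring_polymer(4), membrane_pore(),
                            driving_field("electric_uniform", E = 5e6),
                            langevin_params(dt = 0.02), n_events = 50),
    "n_events")
})
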