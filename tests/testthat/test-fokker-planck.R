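test_that("reflecting evolution conserves mass and relaxes to Boltzmann", {
  pr <- drift_diffusion_problem(10, potential = function(m) 0.05 * (m - 5)^2,
                                boundary_at_0 = "reflecting",
                                boundary_at_N = "reflecting")
  sol <- fp_evolve(pr, t_final = 2000, n_grid = 256, dt = 1,
                   initial = function(m) rep(0.1, length(m)))
  # mass conserved to near round-off over 2000 implicit steps
  expect_lt(max(abs(sol$survival - 1)), 1e-9)
  # long-time profile is the Boltzmann distribution
  P <- sol$P[nrow(sol$P), ]
  eq <- exp(-0.05 * (sol$grid - 5)^2)
  eq <- eq / (sum(eq) * sol$h)
  expect_lt(sum(abs(P - eq)) * sol$h, 1e-6)
  expect_true(all(sol$P >= 0))
})

test_that("discrete continuity links cell masses to face fluxes", {
  pr <- drift_diffusion_problem(10, potential = function(m) 0.3 * m,
                                boundary_at_0 = "reflecting",
                                boundary_at_N = "absorbing")
  dt <- 0.05
  sol <- fp_evolve(pr, t_final = 40 * dt, n_grid = 64, dt = dt,
                   n_store = 41, initial = function(m) rep(0.1, length(m)))
  # implicit Euler: (P^{k+1} - P^k)/dt = -(J_{i+1/2}^{k+1} - J_{i-1/2}^{k+1})/h
  for (k in 2:nrow(sol$P)) {
    lhs <- (sol$P[k, ] - sol$P[k - 1, ]) / dt
    rhs <- -diff(sol$J[k, ]) / sol$h
    expect_lt(max(abs(lhs - rhs)), 1e-9 * max(1, max(abs(rhs))))
  }
})

test_that("flat-potential survival decays at the diffusion eigenrate", {
  N <- 10; D <- 1
  pr <- drift_diffusion_problem(N, diffusion = D)
  sol <- fp_evolve(pr, t_final = 160, n_grid = 256, dt = 0.05,
                   initial = function(m) rep(1 / N, length(m)))
  S <- sol$survival; tg <- sol$step_times
  win <- tg > 60                  # late window: slowest mode only
  rate <- -stats::coef(stats::lm.fit(cbind(1, tg[win]), log(S[win])))[2]
  expect_equal(unname(rate), pi^2 * D / (4 * N^2), tolerance = 0.01)
})

test_that("steady-state flux matches the barrier-integral oracle", {
  # no barrier, constant D = k0: linear profile, J = P0 k0 / N
  pr0 <- drift_diffusion_problem(20, diffusion = 2,
                                 boundary_at_0 = "fixed_value", P0 = 0.5)
  expect_equal(steady_state_flux(pr0, n_grid = 256), 0.5 * 2 / 20,
               tolerance = 1e-6)
  # parabolic barrier with linear friction: cross-module closed form
  pb <- parabolic_barrier(0.01, 1); fr <- friction_model(0.05, 1)
  beta <- 1
  ip <- flux_inputs(pb, fr, N = 100, beta = beta, P0 = 1)
  prb <- drift_diffusion_problem(
    100, diffusion = function(m) 1 / (beta * (fr$c1 * m + fr$c2)),
    potential = pb, beta = beta, boundary_at_0 = "fixed_value", P0 = 1)
  expect_equal(steady_state_flux(prb, n_grid = 1024), flux(ip)$J,
               tolerance = 1e-4)
  # grid convergence: halving the spacing cuts the error by >= 3 (2nd order)
  Jex <- flux(ip)$J
  e1 <- abs(steady_state_flux(prb, n_grid = 128) / Jex - 1)
  e2 <- abs(steady_state_flux(prb, n_grid = 256) / Jex - 1)
  expect_gt(e1 / e2, 3)
})

test_that("raising the barrier by 2 kT suppresses the flux by ~e^2", {
  mkJ <- function(h) {   # barrier of height h at fixed curvature b1
    b1 <- 0.05; N <- 50; b2 <- sqrt(4 * b1 * h)  # peak height b2^2/(4 b1)
    pr <- drift_diffusion_problem(
      N, diffusion = 1, potential = function(m) -b1 * m^2 + b2 * m,
      boundary_at_0 = "fixed_value", P0 = 1)
    steady_state_flux(pr, n_grid = 512)
  }
  ratio <- mkJ(3) / mkJ(5)
  expect_equal(ratio, exp(2), tolerance = 0.2)
})

test_that("MFPT: quadrature and PDE routes agree with classical limits", {
  # flat potential: tau = N^2 / (2 k0)
  pr <- drift_diffusion_problem(20, diffusion = 1)
  mf <- mean_first_passage_time(pr, m_start = 0)
  expect_equal(mf$tau, 20^2 / 2, tolerance = 1e-6)
  expect_lt(mf$relative_difference, 0.01)
  # strong downhill tilt: tau -> N / (k0 beta |F'|)
  pr_t <- drift_diffusion_problem(20, diffusion = 1, drive_force = 5)
  mf_t <- mean_first_passage_time(pr_t)
  expect_equal(mf_t$tau, 20 / 5, tolerance = 0.05)
  # monotone in barrier tilt (stochastic ordering in barrier height)
  taus <- vapply(c(0, 0.1, 0.2), function(b2) {
    prb <- drift_diffusion_problem(20, potential = function(m) b2 * m)
    mean_first_passage_time(prb, check = FALSE)$tau
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("first-passage density integrates to 1 with consistent moments", {
  pr <- drift_diffusion_problem(10, diffusion = 1, drive_force = 2)
  tau <- mean_first_passage_time(pr, check = FALSE)$tau
  tg <- seq(0, 14 * tau, length.out = 3000)
  fp <- first_passage_histogram(pr, time_grid = tg)
  mass <- pracma::trapz(fp$time, fp$density)
  expect_equal(mass, 1, tolerance = 1e-4)
  mom1 <- pracma::trapz(fp$time, fp$time * fp$density)
  expect_equal(mom1, tau, tolerance = 0.01)
  # drifted diffusion first-passage law is positively skewed
  mom2 <- pracma::trapz(fp$time, (fp$time - mom1)^2 * fp$density)
  mom3 <- pracma::trapz(fp$time, (fp$time - mom1)^3 * fp$density)
  expect_gt(mom3 / mom2^1.5, 0)
  expect_true(all(fp$density >= 0))
})

test_that("coordinate change x = a m with G = P/a leaves observables intact", {
  a <- 2; N <- 16; k0 <- 1
  pot_m <- function(m) 0.1 * m
  pr_m <- drift_diffusion_problem(N, diffusion = k0, potential = pot_m,
                                  a = a)
  pr_x <- drift_diffusion_problem(a * N, diffusion = k0,
                                  potential = function(x) pot_m(x / a),
                                  a = 1)
  t_m <- mean_first_passage_time(pr_m, n_grid = 128, check = FALSE)
  t_x <- mean_first_passage_time(pr_x, n_grid = 128, check = FALSE)
  expect_equal(t_m$tau, t_x$tau, tolerance = 1e-8)
  expect_equal(t_m$tau_pde, t_x$tau_pde, tolerance = 1e-8)
  pr_m2 <- drift_diffusion_problem(N, diffusion = k0, potential = pot_m,
                                   a = a, boundary_at_0 = "fixed_value")
  pr_x2 <- drift_diffusion_problem(a * N, diffusion = k0,
                                   potential = function(x) pot_m(x / a),
                                   a = 1, boundary_at_0 = "fixed_value")
  # G = P/a at the pinned inlet: P0 in x-coordinates is P0/a
  pr_x2$P0 <- pr_m2$P0 / a
  expect_equal(steady_state_flux(pr_m2, n_grid = 256),
               steady_state_flux(pr_x2, n_grid = 256), tolerance = 1e-8)
})

test_that("solver rejects ill-posed configurations", {
  expect_error(drift_diffusion_problem(-1), "N must")
  expect_error(fp_evolve(drift_diffusion_problem(10), t_final = 1,
                         n_grid = 8), "n_grid")
  expect_error(steady_state_flux(drift_diffusion_problem(10)),
               "fixed_value")
  expect_error(mean_first_passage_time(
    drift_diffusion_problem(10, boundary_at_0 = "fixed_value")),
    "reflecting")
})
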