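test_that("barrier integrand matches hand evaluation", {
  expect_equal(barrier_integrand(0, fin(0.01, 1, 2, 3, N = 10)), 3)
  expect_equal(barrier_integrand(c(0, 3, 7), fin(0, 0, 0, 1, N = 10)),
               rep(1, 3))
  expect_equal(barrier_integrand(10, fin(0.01, 0, 0, 1, N = 10)), exp(-1))
  expect_error(barrier_integrand(11, fin(0.01, 0, 0, 1, N = 10)), "\\[0, N\\]")
  # sharp rising barrier overflows linearly but not in log space
  steep <- fin(1e-4, 9, 0, 1, N = 400, beta = 5)
  expect_warning(barrier_integrand(400, steep), "overflow")
  expect_true(is.finite(barrier_integrand(400, steep, log = TRUE)))
})

test_that("quadrature reproduces elementary integrals", {
  expect_equal(f_of_N_quadrature(fin(0, 0, 0, 1, N = 10)), 10)
  expect_equal(f_of_N_quadrature(fin(0, 0, 1, 1e-12, N = 10)), 50,
               tolerance = 1e-6)
  # Gaussian integral: (1/2) sqrt(pi/b1) erf(sqrt(b1) N)
  expect_equal(f_of_N_quadrature(fin(0.01, 0, 0, 1, N = 10)),
               0.5 * sqrt(pi / 0.01) * pracma::erf(1), tolerance = 1e-9)
  # prefactor a^2 beta
  expect_equal(f_of_N_quadrature(fin(0, 0, 0, 1, N = 10, a = 2, beta = 3)),
               4 * 3 * 10)
})

test_that("closed-form antiderivative differentiates to the integrand", {
  set.seed(1)
  for (i in 1:25) {
    b1 <- runif(1, 0.05, 0.3); b2 <- runif(1, -1.5, 1.5)
    ip <- fin(b1, b2, runif(1, 0, 3), runif(1, 0.1, 3), N = 20,
              beta = runif(1, 0.5, 1.5))
    # evaluate near the exponent's peak: far from it the antiderivative's
    # large constant term swamps the finite difference in double precision
    m <- min(max(b2 / (2 * b1) + runif(1, -2, 2), 0.5), 19.5)
    expect_equal(num_deriv(function(x) I_closed_form(x, ip), m, h = 1e-4),
                 barrier_integrand(m, ip),
                 tolerance = 1e-6)
  }
  # c1 = 1, c2 = 0, b2 = 0: I(m) - I(0) = 50 (1 - e^{-0.01 m^2})
  ip <- flux_inputs(parabolic_barrier(0.01, 0), friction_model(1, 1e-15),
                    N = 10)
  m <- c(2, 5, 10)
  expect_equal(I_closed_form(m, ip) - I_closed_form(0, ip),
               50 * (1 - exp(-0.01 * m^2)), tolerance = 1e-9)
  expect_error(I_closed_form(1, fin(0, 1, 0, 1, N = 5)), "b1 > 0")
})

test_that("closed form equals quadrature across a broad random sweep", {
  set.seed(101)
  for (i in 1:200) {
    ip <- fin(exp(runif(1, log(1e-4), log(1))), runif(1, -10, 10),
              runif(1, 0, 10), runif(1, 1e-3, 10),
              N = runif(1, 5, 500), beta = exp(runif(1, log(0.1), log(10))))
    expect_equal(f_of_N_closed_form(ip, log = TRUE),
                 f_of_N_quadrature(ip, log = TRUE), tolerance = 1e-8)
  }
})

test_that("flux follows J = P0 / f(N) with the documented limits", {
  # no barrier, constant friction: J = P0 / (a^2 beta c2 N)
  ip <- fin(0, 0, 0, 2, N = 10, beta = 0.5, a = 1.5, P0 = 0.8)
  r <- flux(ip)
  expect_equal(r$method, "quadrature")
  expect_equal(r$J, 0.8 / (1.5^2 * 0.5 * 2 * 10))
  # doubling c2 halves J
  r2 <- flux(fin(0, 0, 0, 4, N = 10, beta = 0.5, a = 1.5, P0 = 0.8))
  expect_equal(r2$J, r$J / 2)
  # P0 = 0 gives J = 0; P0 out of range rejected
  expect_equal(flux(fin(0.01, 1, 0, 1, N = 50, P0 = 0))$J, 0)
  expect_error(fin(0.01, 1, 0, 1, N = 50, P0 = 1.5), "P0")
  # closed form selected automatically when b1 > 0, and recorded
  rc <- flux(fin(0.01, 1, 1, 1, N = 50))
  expect_equal(rc$method, "closed_form")
  expect_lt(rc$relative_disagreement, 1e-8)
  expect_equal(rc$J, rc$P0 / rc$fN)
  # fixed-point hook: inlet emptied by large flux
  rfp <- flux(fin(0, 0, 0, 1, N = 2), p0_map = function(J) 0.5)
  expect_equal(rfp$P0, 0.5)
  expect_equal(rfp$J, 0.5 / rfp$fN)
})

test_that("flux is monotone in barrier tilt and friction", {
  base <- function(b2, c1, c2)
    flux(fin(0.01, b2, c1, c2, N = 50))$J
  J_b2 <- vapply(c(-1, 0, 0.5, 1), base, numeric(1), c1 = 1, c2 = 1)
  expect_true(all(diff(J_b2) < 0))           # taller barrier, smaller flux
  J_c1 <- vapply(c(0, 1, 5), function(c1) base(0.3, c1, 1), numeric(1))
  expect_true(all(diff(J_c1) < 0))
  J_c2 <- vapply(c(0.5, 1, 5), function(c2) base(0.3, 1, c2), numeric(1))
  expect_true(all(diff(J_c2) < 0))
})

test_that("flux scales as 1/a^2 and f(N) grows Arrhenius-like with beta", {
  ip1 <- fin(0.01, 0.5, 1, 1, N = 50, a = 1)
  ip2 <- fin(0.01, 0.5, 1, 1, N = 50, a = 3)
  expect_equal(flux(ip2)$J, flux(ip1)$J / 9)
  # symmetric barrier of height dF: log f - beta dF stays within a narrow
  # band as beta grows (saddle-point prefactor is only algebraic in beta)
  b1 <- 0.02; N <- 50; b2 <- b1 * N       # peak at N/2
  dF <- b2^2 / (4 * b1)
  dev <- vapply(c(2, 5, 10, 20), function(beta) {
    ip <- fin(b1, b2, 0, 1, N = N, beta = beta)
    f_of_N_closed_form(ip, log = TRUE) - beta * dF
  }, numeric(1))
  expect_lt(max(dev) - min(dev), 3)
  expect_lt(max(abs(dev)), 10)
})

test_that("input validation catches non-physical configurations", {
  expect_error(parabolic_barrier(-1, 0), "b1")
  expect_error(friction_model(-0.1, 1), "c1")
  expect_error(fin(0.01, 0, 1, -20, N = 10), "positive on")
  expect_error(flux(fin(0, 0, 0, 1, N = 5), method = "closed_form"),
               "b1 = 0")
})
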