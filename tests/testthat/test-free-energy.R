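test_that("chain statistics presets and custom validation", {
  g <- chain_statistics("gaussian")
  expect_equal(c(g$gamma1, g$gamma2), c(0.5, 0.5))
  expect_equal(chain_statistics("self_avoiding")$gamma1, 0.69)
  expect_equal(chain_statistics("rodlike")$gamma2, 1.0)
  cs <- chain_statistics("custom", gamma1 = 0.4, gamma2 = 0.8)
  expect_equal(cs$gamma2, 0.8)
  expect_error(chain_statistics("custom", gamma1 = 0, gamma2 = 0.5),
               "0 < gamma")
  expect_error(chain_statistics("custom", gamma1 = 0.5, gamma2 = 1.2),
               "0 < gamma")
  expect_error(chain_statistics("custom", gamma1 = 0.5), "both")
})

test_that("entropic free energy matches direct evaluation", {
  # gamma = 1 on both sides kills the log terms, leaving m * delta_mu
  b_rod <- translocation_barrier(2, delta_mu = 0.3,
                                 chain_stats = chain_statistics("rodlike"))
  expect_equal(entropic_free_energy(1, b_rod), 0.3)
  # symmetric gaussian case: F(m) = 0.5 kT ln[m (N - m)]
  expect_equal(entropic_free_energy(1, translocation_barrier(2)), 0)
  expect_equal(entropic_free_energy(2, translocation_barrier(4)),
               0.5 * log(4))
  # asymmetric exponents
  b_as <- translocation_barrier(
    10, kT = 2, chain_stats = chain_statistics("custom", 0.4, 0.8))
  expect_equal(entropic_free_energy(3, b_as),
               2 * (0.6 * log(7) + 0.2 * log(3)))
  expect_error(entropic_free_energy(-1, translocation_barrier(4)),
               "\\[0, N\\]")
  expect_error(entropic_free_energy(5, translocation_barrier(4)),
               "\\[0, N\\]")
  expect_error(translocation_barrier(1), "N must")
})

test_that("free energy is symmetric and shifts linearly with delta_mu", {
  for (N in c(10, 57, 200)) {
    b0 <- translocation_barrier(N)
    m <- seq(0.01 * N, 0.99 * N, length.out = 41)
    expect_equal(entropic_free_energy(m, b0),
                 entropic_free_energy(N - m, b0))
    for (dmu in c(-0.3, 0.12)) {
      bd <- translocation_barrier(N, delta_mu = dmu)
      expect_equal(entropic_free_energy(m, bd) -
                     entropic_free_energy(m, b0), m * dmu)
    }
  }
})

test_that("barrier maximum agrees with grid search and handles flat case", {
  b <- translocation_barrier(100)
  expect_equal(barrier_maximum(b)$m_star, 50)   # symmetric barrier
  bt <- translocation_barrier(100, delta_mu = -0.05)
  mx <- barrier_maximum(bt)
  # exhaustive grid search oracle at step 1e-4 * N
  mg <- seq(1e-4 * 100, 100 - 1e-4 * 100, by = 1e-4 * 100)
  Fg <- entropic_free_energy(mg, bt, clamp = FALSE, delta = 0)
  expect_equal(mx$m_star, mg[which.max(Fg)], tolerance = 1e-3)
  expect_gte(mx$F_star, max(Fg))
  # tilted asymmetric barrier
  ba <- translocation_barrier(
    50, delta_mu = 0.02, chain_stats = chain_statistics("custom", 0.3, 0.7))
  mga <- seq(5e-3, 50 - 5e-3, by = 5e-3)
  Fga <- entropic_free_energy(mga, ba, clamp = FALSE, delta = 0)
  expect_equal(barrier_maximum(ba)$m_star, mga[which.max(Fga)],
               tolerance = 1e-2)
  # rod-like chains: F linear in m, no interior maximum
  expect_error(
    barrier_maximum(translocation_barrier(
      10, delta_mu = 0.1, chain_stats = chain_statistics("rodlike"))),
    class = "translokit_no_interior_maximum")
})

test_that("parabola fit recovers exact coefficients and mid-chain vertex", {
  # identity fit: data generated from an exact parabola
  pb_id <- fit_parabola(function(m) -0.01 * m^2 + 1 * m, m_lo = 10,
                        m_hi = 90, n_samples = 81)
  expect_equal(c(pb_id$b1, pb_id$b2, pb_id$b3), c(0.01, 1, 0),
               tolerance = 1e-10)
  expect_lt(attr(pb_id, "residual_norm"), 1e-9)
  # entropic barrier: symmetry forces the fitted vertex to N/2
  pb <- fit_parabola(translocation_barrier(100))
  expect_gt(pb$b1, 0)
  expect_equal(pb$b2 / (2 * pb$b1), 50, tolerance = 1e-6)
  expect_lt(attr(pb, "residual_norm"), 1)
  expect_error(fit_parabola(translocation_barrier(100), n_samples = 2),
               "n_samples")
  expect_error(fit_parabola(translocation_barrier(100), m_lo = -1),
               "window")
  # convex data: shape error (b1 <= 0)
  expect_error(fit_parabola(function(m) m^2, m_lo = 1, m_hi = 10),
               "not concave")
})

test_that("parabolic difference is b3-independent and exact", {
  pb <- parabolic_barrier(0.01, 1, b3 = 123)
  expect_equal(parabolic_difference(0, pb), 0)
  expect_equal(parabolic_difference(10, pb), 9)
  expect_equal(parabolic_difference(10, parabolic_barrier(0, 0, 5)), 0)
  expect_equal(parabolic_difference(3, pb),
               parabolic_difference(3, parabolic_barrier(0.01, 1, -7)))
})

test_that("barrier profile table has the documented shape", {
  prof <- barrier_profile(translocation_barrier(20), m = c(5, 10, 15))
  expect_named(prof, c("m", "F"))
  expect_equal(prof$F[2], entropic_free_energy(10, translocation_barrier(20)))
})
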