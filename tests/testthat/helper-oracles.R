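# Independent oracles used across the suite.

# Brute-force census of m-step +/-1 walks that never go below the origin
# (feasible up to m ~ 16; the package's dynamic programme must agree).
brute_force_halfspace_walks <- function(m) {
  count <- 0L
  for (mask in 0:(2^m - 1)) {
    steps <- ifelse(bitwAnd(mask, 2^(0:(m - 1))) > 0, 1L, -1L)
    if (all(cumsum(steps) >= 0)) count <- count + 1L
  }
  count
}

# central-difference derivative
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# quick flux inputs builder
fin <- function(b1, b2, c1, c2, N, beta = 1, a = 1, P0 = 1)
  flux_inputs(parabolic_barrier(b1, b2), friction_model(c1, c2),
              a = a, N = N, beta = beta, P0 = P0)
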