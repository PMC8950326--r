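# translokit

Modelling the passage of a linear polymer through a nanometre-scale
membrane pore, for people studying translocation of DNA, RNA and proteins
through nanopores — theorists wanting the analytic barrier/flux layer,
and simulators wanting a seeded, reproducible bead-spring engine.

The package implements three connected layers on the threading coordinate
`m` (the number of monomers that have crossed the pore midpoint):

1. **Free-energy barrier.**  For sub-chains tethered at the wall with
   partition exponents `γ₁, γ₂` (0.5 ideal, ≈0.69 self-avoiding, 1
   rod-like) and a chemical-potential step `Δμ` per segment,

   `βF(m) = (1−γ₁) ln(N−m) + (1−γ₂) ln(m) + m β Δμ`,

   with its maximum, symmetry properties and least-squares parabolic
   surrogate `F(m) = −b₁m² + b₂m + b₃`.

2. **Drift-diffusion (Smoluchowski) dynamics and flux.**  The density
   `P(m,t)` obeys `∂P/∂t = (1/a²) ∂/∂m [D(m)(∂P/∂m + βF′(m)P)]` with an
   absorbing boundary at `m = N`.  In steady state, with linear friction
   `C(m) = c₁m + c₂`, the flux is `J = P₀/f(N)` with
   `f(N) = a²β ∫₀ᴺ C(m) e^{β[F(m)−F(0)]} dm`, evaluated both by adaptive
   quadrature and by an exact erf-based antiderivative (stabilised with
   the scaled complementary error function; the two routes agree to
   1e-8 across sweeps of 10³ random parameter sets).  A finite-volume
   solver (exponentially fitted, positivity-preserving) provides
   transients, first-passage densities and mean escape times.

3. **Langevin bead-spring simulator.**  Charged chains driven through a
   slit pore by an electric field (in-pore or uniform) or a constant end
   force, integrated with the exact Ornstein–Uhlenbeck propagator of
   `dv = M⁻¹F dt − γv dt + √(2γkT) M^{−1/2} dW`; escape times, their
   histograms (near-Gaussian when strongly driven, long exponential tails
   when weakly driven) and their scaling with `E` and `N`.

A scaling module estimates the exponents the model is built on: the
partition exponent `γ = 0.5` from an exact big-integer census of
wall-tethered walks, the Flory exponent `ν ≈ 0.588` from pivot-sampled 3-D
self-avoiding walks, and the strong-force escape-time exponent 2 in
`τ_N ~ N²/F`.

## Worked example

```r
library(translokit)

# a 100-mer ideal chain with a favourable chemical-potential step
b <- translocation_barrier(N = 100, delta_mu = -0.05)
barrier_maximum(b)
#> $m_star
#> [1] 9.009805
#> $F_star
#> [1] 2.904042

# parabolic surrogate and steady-state flux through it
pb <- fit_parabola(translocation_barrier(100))
ip <- flux_inputs(pb, friction_model(0.05, 1), N = 100, beta = 1, P0 = 1)
flux(ip)
#> <flux_result> J=0.00171423  f(N)=583.351 (log 6.36879)  method=closed_form
#>   closed-form vs quadrature relative disagreement: 0
```

The tilted barrier peaks at `m* ≈ 9` monomers (2.9 kT high): once ~9
monomers are through, the chemical-potential gain outweighs the entropic
cost and translocation runs downhill.  The steady-state flux through the
parabolic surrogate is `J ≈ 1.7e-3` chains per unit time per unit inlet
probability, and the closed form agrees with numerical quadrature to
machine precision.

Simulation side:

```r
ev <- run_translocation(bead_spring_polymer(32), membrane_pore(),
                        driving_field("end_force", end_force_f = 10),
                        langevin_params(dt = 0.02), seed = 42)
ev$tau        # escape time of this seeded event, reduced time units
```

## Command line

A thin wrapper over the same functions ships in `inst/cli/translokit.R`:

```sh
Rscript inst/cli/translokit.R flux --config cfg.yaml --out flux.json
Rscript inst/cli/translokit.R scan --config scan.yaml --out surface.csv
Rscript inst/cli/translokit.R render-surface --input surface.csv --out surface.png
```

Configs are YAML or JSON with `engine`, `seed` and an engine-specific
`parameters` block; validation reports every problem at once.

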