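#' Langevin integrator parameters
#'
#' Constants of the stochastic equation of motion
#' `dv = M^-1 F(x) dt - gamma v dt + sqrt(2 gamma kT) M^-1/2 dW(t)`,
#' integrated with the exact Ornstein-Uhlenbeck propagator over each step
#' (force frozen at the step start).  Noise amplitude is wired to the damping
#' through the fluctuation-dissipation relation `kT D^-1 = gamma M`.
#' Identical seeds give bit-identical trajectories.
#'
#' @param gamma_damp damping rate (1/time, >= 0).
#' @param kT thermal energy.
#' @param mass per-bead mass (diagonal).
#' @param dt time step (> 0).
#' @param seed integer RNG seed.
#' @param noise_on include the thermal noise?  With `FALSE` and a constant
#'   force the update is the deterministic exponential-kernel recurrence.
#' @export
langevin_params <- function(gamma_damp = 1, kT = 1, mass = 1, dt = 0.01,
                            seed = 1L, noise_on = TRUE) {
  if (gamma_damp < 0) stop("gamma_damp must be >= 0")
  if (dt <= 0) stop("dt must be positive")
  if (mass <= 0) stop("mass must be positive")
  if (kT < 0) stop("kT must be >= 0")
  structure(list(gamma_damp = gamma_damp, kT = kT, mass = mass, dt = dt,
                 seed = as.numeric(seed), noise_on = isTRUE(noise_on)),
            class = "langevin_params")
}

#' Bead-spring polymer state
#'
#' A linear chain of `N` beads joined by harmonic bonds of rest length
#' `bond_length` (the monomer size `a`; chain length `l = N a`).  Positions
#' default to a straight rod along x.  Excluded volume is off by default
#' (ideal chain); `"purely_repulsive"` adds a soft repulsive pair potential
#' for self-avoiding runs.
#'
#' @param N bead count (>= 1).
#' @param dimension 2 or 3.
#' @param bond_k harmonic bond stiffness.
#' @param bond_length equilibrium bond length `a`.
#' @param charge per-bead charge (reduced units; used by electric driving).
#' @param excluded_volume `"off"` or `"purely_repulsive"`.
#' @param positions,velocities optional `dimension x N` matrices.
#' @export
bead_spring_polymer <- function(N, dimension = 2, bond_k = 25,
                                bond_length = 1, charge = 1,
                                excluded_volume = c("off", "purely_repulsive"),
                                positions = NULL, velocities = NULL) {
  excluded_volume <- match.arg(excluded_volume)
  if (N < 1 || N != floor(N)) stop("N must be a positive integer")
  if (!dimension %in% c(2, 3)) stop("dimension must be 2 or 3")
  if (is.null(positions)) {
    positions <- matrix(0, dimension, N)
    positions[1, ] <- (seq_len(N) - 1) * bond_length
  }
  if (is.null(velocities)) velocities <- matrix(0, dimension, N)
  stopifnot(is.matrix(positions), nrow(positions) == dimension,
            ncol(positions) == N,
            is.matrix(velocities), all(dim(velocities) == dim(positions)))
  structure(list(N = as.integer(N), dimension = as.integer(dimension),
                 bond_k = bond_k, bond_length = bond_length, charge = charge,
                 excluded_volume = excluded_volume,
                 positions = positions, velocities = velocities),
            class = "bead_spring_polymer")
}

#' Membrane with a nanopore
#'
#' An impenetrable wall slab normal to the x axis with a centred opening
#' (slit in 2-D, cylinder in 3-D) of half-width `pore_radius`.  Beads inside
#' the slab whose transverse coordinate lies outside the opening feel a
#' half-harmonic repulsion of stiffness `wall_k` along x from the nearest
#' face.  The crossing coordinate `m` counts beads past the pore midpoint.
#'
#' @param wall_position x coordinate of the cis face.
#' @param wall_thickness slab thickness along x.
#' @param pore_radius opening half-width (>= bond_length/2 so the chain can
#'   thread; checked when combined with a polymer).
#' @param wall_k repulsion stiffness.
#' @export
membrane_pore <- function(wall_position = 0, wall_thickness = 0.5,
                          pore_radius = 1, wall_k = 100) {
  if (wall_thickness <= 0 || pore_radius <= 0 || wall_k < 0)
    stop("wall_thickness, pore_radius must be positive; wall_k >= 0")
  structure(list(wall_position = wall_position,
                 wall_thickness = wall_thickness,
                 pore_radius = pore_radius, wall_k = wall_k),
            class = "membrane_pore")
}

#' Reduced driving force from an SI electric field
#'
#' Maps a field strength in V/m to the dimensionless force unit of the
#' simulation (kT/a with `a` = 1 nm at T = 295 K): `f* = q_eff e E a / kT`.
#' The default effective charge of 25 elementary charges per bead reflects a
#' coarse-grained segment carrying many ionised groups, and places the
#' 1e6-7e6 V/m range at reduced forces of order 1-7.
#'
#' @param E field strength, V/m (vectorised).
#' @param q_eff effective elementary charges per bead.
#' @param a bead (monomer) size in metres.
#' @param temperature Kelvin.
#' @export
efield_reduced_force <- function(E, q_eff = 25, a = 1e-9,
                                 temperature = 295) {
  kB <- 1.380649e-23; e <- 1.602176634e-19
  q_eff * e * E * a / (kB * temperature)
}

#' Driving field acting on the chain
#'
#' Exactly one mode: `"electric_in_pore"` (force `q E` on beads inside the
#' pore slab — the potential drop is assumed to be across the pore),
#' `"electric_uniform"` (same force on every bead), `"end_force"` (constant
#' force on the leading bead), or `"none"`.  Electric fields are given in
#' V/m and converted with [efield_reduced_force()]; the end force is given
#' directly in reduced units.
#'
#' @param mode driving mode.
#' @param E field strength in V/m (electric modes).
#' @param q_eff effective elementary charges per bead for the SI mapping.
#' @param end_force_f constant end force, reduced units (`end_force` mode).
#' @param viscosity_eta solvent viscosity, Pa s (only used by the Stokes
#'   mapping helpers; the engine itself is dimensionless).
#' @export
driving_field <- function(mode = c("none", "electric_in_pore",
                                   "electric_uniform", "end_force"),
                          E = NULL, q_eff = 25, end_force_f = NULL,
                          viscosity_eta = NULL) {
  mode <- match.arg(mode)
  f <- 0
  if (mode %in% c("electric_in_pore", "electric_uniform")) {
    if (is.null(E)) stop("electric modes require the field strength E")
    f <- efield_reduced_force(E, q_eff = q_eff)
  } else if (mode == "end_force") {
    if (is.null(end_force_f)) stop("end_force mode requires end_force_f")
    f <- end_force_f
  }
  structure(list(mode = mode, E = E, q_eff = q_eff, force = f,
                 viscosity_eta = viscosity_eta),
            class = "driving_field")
}

.drive_mode_code <- function(field) {
  switch(field$mode, none = 0L, electric_uniform = 1L,
         electric_in_pore = 2L, end_force = 3L)
}

#' Steady drift velocity from the Stokes/Coulomb force balance
#'
#' Balancing the Coulomb force `q E` against the Stokes drag `6 pi eta a v`
#' on a sphere of radius `a` gives `v = q E / (6 pi eta a)`.
#'
#' @param q charge (C).
#' @param E field (V/m).
#' @param eta viscosity (Pa s, > 0).
#' @param a monomer radius (m, > 0).
#' @export
stokes_drift_velocity <- function(q, E, eta, a) {
  if (any(eta <= 0)) stop("eta must be positive")
  if (any(a <= 0)) stop("a must be positive")
  q * E / (6 * pi * eta * a)
}

#' Advance a bead-spring chain by Langevin steps
#'
#' Applies `n_steps` exact-propagator Langevin steps to the chain, with
#' forces (bonds, optional pore wall, optional driving) evaluated at each
#' step's start.
#'
#' @param polymer a [bead_spring_polymer()].
#' @param params a [langevin_params()].
#' @param pore optional [membrane_pore()].
#' @param field optional [driving_field()].
#' @param n_steps number of steps.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return the advanced polymer (same class, updated positions/velocities).
#' @export
langevin_step <- function(polymer, params, pore = NULL, field = NULL,
                          n_steps = 1, seed = params$seed) {
  stopifnot(inherits(polymer, "bead_spring_polymer"),
            inherits(params, "langevin_params"))
  if (!is.null(pore) && pore$pore_radius < polymer$bond_length / 2)
    stop("pore_radius must be >= bond_length/2 for the chain to thread")
  if (is.null(field)) field <- driving_field("none")
  if (any(!is.finite(polymer$positions)))
    stop("non-finite bead position; refusing to step")
  res <- .cpp_lv_chain(
    polymer$positions, polymer$velocities, as.numeric(n_steps),
    params$dt, params$gamma_damp, params$kT, params$mass,
    polymer$bond_k, polymer$bond_length,
    polymer$excluded_volume == "purely_repulsive", polymer$bond_k,
    polymer$bond_length,
    !is.null(pore),
    if (is.null(pore)) 0 else pore$wall_position,
    if (is.null(pore)) 1 else pore$wall_thickness,
    if (is.null(pore)) 1 else pore$pore_radius,
    if (is.null(pore)) 0 else pore$wall_k,
    .drive_mode_code(field), field$force,
    FALSE, params$noise_on, FALSE, as.numeric(seed))
  polymer$positions <- res$positions
  polymer$velocities <- res$velocities
  polymer
}

# straight-rod start on the cis side with bead 1 at the pore mouth,
# then equilibration with bead 1 held (timing starts at release)
.init_chain_at_pore <- function(polymer, pore, params, seed) {
  N <- polymer$N; a <- polymer$bond_length
  pos <- matrix(0, polymer$dimension, N)
  pos[1, ] <- pore$wall_position - (seq_len(N) - 1) * a
  vel <- matrix(0, polymer$dimension, N)
  t_relax <- 10 * N * params$gamma_damp * params$mass /
    max(polymer$bond_k, 1e-12)
  n_eq <- max(10L, ceiling(t_relax / params$dt))
  res <- .cpp_lv_chain(
    pos, vel, as.numeric(n_eq), params$dt, params$gamma_damp, params$kT,
    params$mass, polymer$bond_k, a,
    polymer$excluded_volume == "purely_repulsive", polymer$bond_k, a,
    TRUE, pore$wall_position, pore$wall_thickness, pore$pore_radius,
    pore$wall_k, 0L, 0, TRUE, params$noise_on, FALSE, as.numeric(seed))
  polymer$positions <- res$positions
  polymer$velocities <- res$velocities
  polymer
}

#' Simulate one translocation event
#'
#' Equilibrates the chain on the cis side with the leading bead held at the
#' pore mouth, releases it under the driving field, and steps until every
#' bead has passed the pore midpoint (success) or `max_time` elapses.
#' Identical inputs and seed give an identical event.
#'
#' @param polymer a [bead_spring_polymer()].
#' @param pore a [membrane_pore()].
#' @param field a [driving_field()].
#' @param params a [langevin_params()].
#' @param max_time simulation-time budget for the event.
#' @param seed RNG seed for this event.
#' @return object of class `translocation_event`: `t_entry` (0, release),
#'   `t_exit`, `tau`, `success`, `n_steps`, `seed`, `m_final`.
#' @export
run_translocation <- function(polymer, pore, field, params,
                              max_time = 1e4, seed = params$seed) {
  stopifnot(inherits(polymer, "bead_spring_polymer"),
            inherits(pore, "membrane_pore"),
            inherits(field, "driving_field"),
            inherits(params, "langevin_params"))
  if (pore$pore_radius < polymer$bond_length / 2)
    stop("pore_radius must be >= bond_length/2 for the chain to thread")
  polymer <- .init_chain_at_pore(polymer, pore, params,
                                 seed = as.numeric(seed))
  max_steps <- ceiling(max_time / params$dt)
  res <- .cpp_lv_chain(
    polymer$positions, polymer$velocities, as.numeric(max_steps),
    params$dt, params$gamma_damp, params$kT, params$mass,
    polymer$bond_k, polymer$bond_length,
    polymer$excluded_volume == "purely_repulsive", polymer$bond_k,
    polymer$bond_length,
    TRUE, pore$wall_position, pore$wall_thickness, pore$pore_radius,
    pore$wall_k, .drive_mode_code(field), field$force,
    FALSE, params$noise_on, TRUE, as.numeric(seed) + 7777777)
  tau <- res$steps_done * params$dt
  structure(list(t_entry = 0, t_exit = if (res$crossed) tau else NA_real_,
                 tau = if (res$crossed) tau else NA_real_,
                 success = res$crossed, n_steps = res$steps_done,
                 seed = seed, m_final = res$m_count,
                 timeout = if (res$crossed) NA_real_ else max_time),
            class = "translocation_event")
}

#' @export
print.translocation_event <- function(x, ...) {
  cat(sprintf("<translocation_event> success=%s tau=%s n_steps=%g seed=%s\n",
              x$success, format(x$tau), x$n_steps, format(x$seed)))
  invisible(x)
}

#' Mean escape time over a grid of field strength and chain length
#'
#' Runs `replicates` independent seeded translocation events in every
#' `(E, N)` cell and reports the mean and standard deviation of the escape
#' time plus the success count.  Default ranges mirror the driven
#' simulations: `E` in `[1e6, 7e6]` V/m, `N` in `[5, 50]`.  Cells where all
#' replicates time out are flagged, not dropped.
#'
#' The default driving mode is the uniform field (every charged bead feels
#' `q E`): the scan stays well-driven across the whole grid, so cells remain
#' affordable.  With `mode = "electric_in_pore"` only the bead(s) inside the
#' pore slab are driven and weak-field/long-chain cells become
#' diffusion-dominated and far slower.
#'
#' @param E_values field strengths, V/m.
#' @param N_values chain lengths.
#' @param replicates events per cell (>= 1).
#' @param params a [langevin_params()].
#' @param pore a [membrane_pore()].
#' @param mode driving mode (an electric mode).
#' @param q_eff effective charges per bead for the SI mapping.
#' @param max_time per-event time budget.
#' @param seed base seed; event seeds are derived deterministically.
#' @return data.frame: `E`, `N`, `mean_tau`, `sd_tau`, `n_success`,
#'   `flagged`.
#' @export
escape_time_surface <- function(E_values = seq(1e6, 7e6, length.out = 4),
                                N_values = c(5, 20, 50), replicates = 8,
                                params = langevin_params(dt = 0.02),
                                pore = membrane_pore(),
                                mode = "electric_uniform", q_eff = 25,
                                max_time = 2e4, seed = 1L) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (!length(E_values) || !length(N_values))
    stop("E_values and N_values must be non-empty")
  rows <- list(); r <- 0L
  for (E in E_values) for (N in N_values) {
    field <- driving_field(mode, E = E, q_eff = q_eff)
    poly <- bead_spring_polymer(N, bond_length = 1)
    taus <- vapply(seq_len(replicates), function(rep) {
      ev <- run_translocation(poly, pore, field, params,
                              max_time = max_time,
                              seed = seed * 1e6 + r * 1e4 + rep)
      if (ev$success) ev$tau else NA_real_
    }, numeric(1))
    ok <- !is.na(taus)
    r <- r + 1L
    rows[[r]] <- data.frame(
      E = E, N = N,
      mean_tau = if (any(ok)) mean(taus[ok]) else NA_real_,
      sd_tau = if (sum(ok) > 1) stats::sd(taus[ok]) else NA_real_,
      n_success = sum(ok), flagged = !any(ok))
  }
  out <- do.call(rbind, rows)
  if (any(out$flagged))
    warning("cells with zero successful events are flagged")
  out
}

# sample skewness (g1)
.skewness <- function(x) {
  n <- length(x); mu <- mean(x); s <- sqrt(mean((x - mu)^2))
  mean((x - mu)^3) / s^3
}

#' Escape-time histogram with shape statistics
#'
#' Runs seeded translocation events and summarises the escape-time
#' distribution: histogram, mean, standard deviation, skewness, and an
#' exponential fit to the upper-decile tail (rate from the mean excess over
#' the 90th percentile).  Weakly driven chains develop a long exponential
#' tail (positive skew); strongly driven ones are nearly Gaussian.
#'
#' @param polymer a [bead_spring_polymer()].
#' @param pore a [membrane_pore()].
#' @param field a [driving_field()].
#' @param params a [langevin_params()].
#' @param n_events number of events (>= 100).
#' @param max_time per-event budget.
#' @param seed base seed.
#' @param breaks passed to [graphics::hist()] (computed, not plotted).
#' @return list: `tau` (successful escape times), `histogram`, `mean`, `sd`,
#'   `skewness`, `tail_rate`, `tail_threshold`, `n_success`, `n_events`.
#' @export
translocation_histogram <- function(polymer, pore, field, params,
                                    n_events = 200, max_time = 2e4,
                                    seed = 1L, breaks = "FD") {
  if (n_events < 100) stop("n_events must be >= 100 for stable statistics")
  taus <- vapply(seq_len(n_events), function(i) {
    ev <- run_translocation(polymer, pore, field, params,
                            max_time = max_time, seed = seed * 1e6 + i)
    if (ev$success) ev$tau else NA_real_
  }, numeric(1))
  tau <- taus[!is.na(taus)]
  if (length(tau) < 100)
    stop("fewer than 100 successful events (", length(tau),
         "); statistics refused")
  thr <- stats::quantile(tau, 0.9, names = FALSE)
  excess <- tau[tau > thr] - thr
  hist_obj <- if (stats::sd(tau) == 0) NULL else
    graphics::hist(tau, breaks = breaks, plot = FALSE)
  list(tau = tau, histogram = hist_obj, mean = mean(tau),
       sd = stats::sd(tau), skewness = .skewness(tau),
       tail_rate = if (length(excess) > 1) 1 / mean(excess) else NA_real_,
       tail_threshold = thr, n_success = length(tau), n_events = n_events)
}

#' Single-bead Langevin trajectory (diagnostics)
#'
#' One 1-D bead under optional constant force and harmonic tether, sampled
#' every `stride` steps.  Used for the physics checks: equipartition
#' (velocity variance `kT/M`), mobility (mean velocity `f/(M gamma)`), and
#' the harmonic-well position variance `kT/k`.
#'
#' @param n_samples samples to collect.
#' @param stride steps between samples.
#' @param params a [langevin_params()].
#' @param f_const constant force.
#' @param k_spring harmonic tether stiffness about 0.
#' @param x0,v0 initial condition.
#' @param seed RNG seed.
#' @return list with vectors `x`, `v`.
#' @export
ou_single_trajectory <- function(n_samples, stride = 1,
                                 params = langevin_params(),
                                 f_const = 0, k_spring = 0, x0 = 0, v0 = 0,
                                 seed = params$seed) {
  .cpp_lv_single(as.integer(n_samples), as.integer(stride),
                 params$gamma_damp, params$kT, params$mass, params$dt,
                 f_const, k_spring, x0, v0, params$noise_on,
                 as.numeric(seed))
}

#' First-passage times of a single bead over a parabolic barrier
#'
#' Langevin dynamics of one 1-D bead in the concave potential
#' `U(x) = -b1 x^2 + b2 x`, reflected at 0 and absorbed at `L`.  In the
#' high-friction limit the mean first-passage time matches the Smoluchowski
#' result at matched `D = kT/(M gamma)`.
#'
#' @param n_events number of events.
#' @param b1,b2 barrier coefficients.
#' @param L absorbing boundary.
#' @param params a [langevin_params()].
#' @param x0 start position.
#' @param max_time per-event budget.
#' @param seed RNG seed.
#' @return numeric vector of first-passage times (`NA` = timeout).
#' @export
langevin_barrier_fpt <- function(n_events, b1, b2, L,
                                 params = langevin_params(), x0 = 0,
                                 max_time = 1e5, seed = params$seed) {
  .cpp_lv_barrier_fpt(as.integer(n_events), b1, b2, L, params$gamma_damp,
                      params$kT, params$mass, params$dt, x0,
                      ceiling(max_time / params$dt), params$noise_on,
                      as.numeric(seed))
}
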