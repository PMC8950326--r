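#' Drift-diffusion (Smoluchowski) problem over the threading coordinate
#'
#' Describes the overdamped evolution of the probability density `P(m, t)`:
#' `dP/dt = (1/a^2) d/dm [ D(m) (dP/dm + beta dF/dm P) ]` on `m in [0, N]`.
#' With `a = 1` and constant `D = k0` this is the nucleation-style rate
#' equation for the number of translocated segments; the `1/a^2` prefactor
#' carries the monomer size when the coordinate is read as a length `x = a m`
#' (then `G(x, t) = P(m, t)/a` solves the same equation in `x`).
#'
#' @param N domain length in threading-coordinate units.
#' @param diffusion constant `k0` or a function `D(m) > 0`.
#' @param potential free energy `F(m)`: a function, a
#'   [translocation_barrier()] (evaluated with its endpoint clamp), or a
#'   [parabolic_barrier()].
#' @param beta inverse thermal energy.
#' @param a monomer size entering the `1/a^2` prefactor.
#' @param drive_force optional constant driving force along `m`; implemented
#'   as an extra potential term `-drive_force * m` (kept separate from the
#'   free energy to avoid the symbol clash with `F(m)`).
#' @param boundary_at_0 `"reflecting"` (zero flux; the chain cannot unthread
#'   below `m = 0`) or `"fixed_value"` (density pinned to `P0`, the
#'   steady-state inlet condition).
#' @param boundary_at_N `"absorbing"` (complete translocation is
#'   irreversible, `P(N, t) = 0`) or `"reflecting"` (used for equilibrium
#'   checks).
#' @param P0 pinned inlet density for `boundary_at_0 = "fixed_value"`.
#' @return object of class `drift_diffusion_problem`.
#' @export
drift_diffusion_problem <- function(N, diffusion = 1,
                                    potential = function(m) 0 * m,
                                    beta = 1, a = 1, drive_force = 0,
                                    boundary_at_0 = c("reflecting",
                                                      "fixed_value"),
                                    boundary_at_N = c("absorbing",
                                                      "reflecting"),
                                    P0 = 1) {
  boundary_at_0 <- match.arg(boundary_at_0)
  boundary_at_N <- match.arg(boundary_at_N)
  if (!is.numeric(N) || N <= 0) stop("N must be positive")
  if (!is.numeric(beta) || beta <= 0) stop("beta must be positive")
  if (!is.numeric(a) || a <= 0) stop("a must be positive")
  Dfun <- if (is.function(diffusion)) diffusion else {
    if (!is.numeric(diffusion) || diffusion <= 0)
      stop("constant diffusion must be positive")
    k0 <- diffusion
    function(m) rep_len(k0, length(m))
  }
  Ffun <- if (is.function(potential)) potential
  else if (inherits(potential, "translocation_barrier"))
    function(m) entropic_free_energy(m, potential)
  else if (inherits(potential, "parabolic_barrier"))
    function(m) -potential$b1 * m^2 + potential$b2 * m + potential$b3
  else stop("potential must be a function or a barrier object")
  if (drive_force != 0) {
    base_F <- Ffun
    Ffun <- function(m) base_F(m) - drive_force * m
  }
  structure(list(N = N, D = Dfun, F = Ffun, beta = beta, a = a,
                 boundary_at_0 = boundary_at_0,
                 boundary_at_N = boundary_at_N, P0 = P0),
            class = "drift_diffusion_problem")
}

# Bernoulli function B(w) = w / (e^w - 1), the exponential-fitting weight of
# the Scharfetter-Gummel flux; series branch avoids 0/0 at small |w|
.bernoulli_B <- function(w) {
  out <- numeric(length(w))
  small <- abs(w) < 1e-5
  out[small] <- 1 - w[small] / 2 + w[small]^2 / 12
  out[!small] <- w[!small] / expm1(w[!small])
  out
}

# Assemble the spatial operator: dP/dt = L P + s on cell averages.
# Exponentially fitted finite volume, uniform grid of n cells.
.fp_operator <- function(problem, n_grid) {
  N <- problem$N; h <- N / n_grid
  centers <- (seq_len(n_grid) - 0.5) * h
  faces <- seq(0, N, by = h)
  beta <- problem$beta
  Fc <- problem$F(centers)
  D_face <- problem$D(faces)
  if (any(D_face <= 0)) stop("diffusion must be positive on [0, N]")
  pref <- D_face / (problem$a^2 * h)   # flux prefactor per face
  lower <- numeric(n_grid); diag_ <- numeric(n_grid); upper <- numeric(n_grid)
  s <- numeric(n_grid)
  # interior faces i = 2..n_grid (between cells i-1 and i)
  w <- beta * diff(Fc)
  Bw <- .bernoulli_B(w); Bmw <- .bernoulli_B(-w)
  # face k (k = 2..n_grid) flux: J_k = pref[k] (Bw[k-1] P_{k-1} - Bmw[k-1] P_k)
  # dP_i/dt = -(J_{i+1} - J_i)/h
  for (i in seq_len(n_grid)) {
    if (i > 1) {           # inflow face i
      lower[i] <- pref[i] * Bw[i - 1] / h
      diag_[i] <- diag_[i] - pref[i] * Bmw[i - 1] / h
    }
    if (i < n_grid) {      # outflow face i+1
      diag_[i] <- diag_[i] - pref[i + 1] * Bw[i] / h
      upper[i] <- pref[i + 1] * Bmw[i] / h
    }
  }
  # boundary at 0 (face 1), half-cell to the boundary point
  if (problem$boundary_at_0 == "fixed_value") {
    w0 <- beta * (Fc[1] - problem$F(0))
    pref0 <- problem$D(0) / (problem$a^2 * (h / 2))
    # J_1 = pref0 (B(w0) P0 - B(-w0) P_1)
    diag_[1] <- diag_[1] - pref0 * .bernoulli_B(-w0) / h
    s[1] <- s[1] + pref0 * .bernoulli_B(w0) * problem$P0 / h
  } # reflecting: J_1 = 0, nothing to add
  # boundary at N (face n_grid + 1)
  if (problem$boundary_at_N == "absorbing") {
    wN <- beta * (problem$F(N) - Fc[n_grid])
    prefN <- problem$D(N) / (problem$a^2 * (h / 2))
    # J_{n+1} = prefN (B(wN) P_n - B(-wN) * 0)
    diag_[n_grid] <- diag_[n_grid] - prefN * .bernoulli_B(wN) / h
  }
  list(lower = lower, diag = diag_, upper = upper, s = s,
       centers = centers, faces = faces, h = h, pref = pref,
       Bw = Bw, Bmw = Bmw, Fc = Fc)
}

# Thomas solve of (I - dt L) x = rhs with L tridiagonal (lower/diag/upper).
.fp_tridiag_factor <- function(op, dt) {
  n <- length(op$diag)
  a <- -dt * op$lower          # sub-diagonal of system (a[1] unused)
  b <- 1 - dt * op$diag        # diagonal
  c <- -dt * op$upper          # super-diagonal (c[n] unused)
  cp <- numeric(n); denom <- numeric(n)
  denom[1] <- b[1]; cp[1] <- c[1] / b[1]
  for (i in 2:n) {
    denom[i] <- b[i] - a[i] * cp[i - 1]
    cp[i] <- c[i] / denom[i]
  }
  list(a = a, cp = cp, denom = denom, n = n)
}

.fp_tridiag_solve <- function(fac, rhs) {
  n <- fac$n
  dp <- numeric(n)
  dp[1] <- rhs[1] / fac$denom[1]
  for (i in 2:n) dp[i] <- (rhs[i] - fac$a[i] * dp[i - 1]) / fac$denom[i]
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - fac$cp[i] * x[i + 1]
  x
}

# fluxes at all faces from a density vector
.fp_face_flux <- function(op, P, problem) {
  n <- length(P); h <- op$h
  J <- numeric(n + 1)
  J[2:n] <- op$pref[2:n] * (op$Bw * P[-n] - op$Bmw * P[-1])
  if (problem$boundary_at_0 == "fixed_value") {
    w0 <- problem$beta * (op$Fc[1] - problem$F(0))
    pref0 <- problem$D(0) / (problem$a^2 * (h / 2))
    J[1] <- pref0 * (.bernoulli_B(w0) * problem$P0 - .bernoulli_B(-w0) * P[1])
  }
  if (problem$boundary_at_N == "absorbing") {
    wN <- problem$beta * (problem$F(problem$N) - op$Fc[n])
    prefN <- problem$D(problem$N) / (problem$a^2 * (h / 2))
    J[n + 1] <- prefN * .bernoulli_B(wN) * P[n]
  }
  J
}

# default initial condition: delta at m_start, realised as a single full cell
.fp_initial <- function(problem, op, initial, m_start) {
  n <- length(op$centers)
  if (is.function(initial)) {
    P <- initial(op$centers)
    if (any(P < 0)) stop("initial condition must be non-negative")
    return(P)
  }
  P <- numeric(n)
  i0 <- min(max(1L, 1L + floor(m_start / op$h)), n)
  P[i0] <- 1 / op$h
  P
}

#' Evolve the drift-diffusion problem in time
#'
#' Exponentially fitted (Scharfetter-Gummel) finite-volume discretisation on
#' a uniform grid with implicit-Euler time stepping.  The scheme is
#' drift-robust, positivity-preserving and conserves mass exactly under
#' reflecting boundaries.
#'
#' @param problem a [drift_diffusion_problem()].
#' @param t_final final time.
#' @param n_grid number of cells (>= 16), default 512.
#' @param dt time step, default `t_final / 1000`.
#' @param n_store number of (evenly spaced) stored snapshots.
#' @param initial initial density as a function of `m`, or `NULL` for a
#'   delta at `m_start`.
#' @param m_start location of the default delta initial condition.
#' @return object of class `solution_field`: `grid` (cell centers), `times`,
#'   `P` (matrix, snapshots in rows), `J` (face fluxes per snapshot),
#'   `faces`, `survival` (total mass at every time step) and `step_times`.
#' @export
fp_evolve <- function(problem, t_final, n_grid = 512, dt = t_final / 1000,
                      n_store = 101, initial = NULL, m_start = 0) {
  stopifnot(inherits(problem, "drift_diffusion_problem"))
  if (n_grid < 16) stop("n_grid must be >= 16")
  if (dt <= 0 || t_final <= 0) stop("dt and t_final must be positive")
  op <- .fp_operator(problem, n_grid)
  fac <- .fp_tridiag_factor(op, dt)
  n_steps <- max(1L, ceiling(t_final / dt))
  store_at <- unique(pmax(1L, round(seq(1L, n_steps, length.out = n_store))))
  P <- .fp_initial(problem, op, initial, m_start)
  Pmat <- matrix(NA_real_, nrow = length(store_at) + 1, ncol = n_grid)
  Jmat <- matrix(NA_real_, nrow = length(store_at) + 1, ncol = n_grid + 1)
  Pmat[1, ] <- P
  Jmat[1, ] <- .fp_face_flux(op, P, problem)
  survival <- numeric(n_steps + 1)
  survival[1] <- sum(P) * op$h
  k <- 2L
  for (step in seq_len(n_steps)) {
    P <- .fp_tridiag_solve(fac, P + dt * op$s)
    if (any(P < -1e-9 * max(abs(P))))
      stop("scheme produced negative density beyond tolerance")
    survival[step + 1] <- sum(P) * op$h
    if (k <= length(store_at) + 1 && store_at[k - 1L] == step) {
      Pmat[k, ] <- P
      Jmat[k, ] <- .fp_face_flux(op, P, problem)
      k <- k + 1L
    }
  }
  structure(list(grid = op$centers, faces = op$faces, h = op$h,
                 times = c(0, store_at * dt), P = Pmat, J = Jmat,
                 step_times = seq(0, n_steps) * dt, survival = survival,
                 dt = dt, problem = problem),
            class = "solution_field")
}

#' Steady-state flux through the pore from the discretised problem
#'
#' Solves the stationary two-point problem with the density pinned to `P0`
#' at `m = 0` and absorbed at `m = N`, and returns the (constant) flux.  For
#' parabolic barriers this matches the closed-form `J = P0 / f(N)` of the
#' flux module; for arbitrary barriers it matches the quadrature of the
#' barrier integral.
#'
#' @param problem a [drift_diffusion_problem()] with
#'   `boundary_at_0 = "fixed_value"` and `boundary_at_N = "absorbing"`.
#' @param n_grid grid resolution, default 1024.
#' @export
steady_state_flux <- function(problem, n_grid = 1024) {
  stopifnot(inherits(problem, "drift_diffusion_problem"))
  if (problem$boundary_at_0 != "fixed_value" ||
      problem$boundary_at_N != "absorbing")
    stop("steady state needs fixed_value at 0 and absorbing at N")
  op <- .fp_operator(problem, n_grid)
  # solve L P + s = 0  via (I - big*L) P = big*s with a huge implicit step
  n <- n_grid
  a <- op$lower; b <- op$diag; c <- op$upper
  # direct tridiagonal solve of (-L) P = s
  cp <- numeric(n); dp <- numeric(n)
  bb <- -b; aa <- -a; cc <- -c
  denom <- bb[1]; cp[1] <- cc[1] / denom; dp[1] <- op$s[1] / denom
  for (i in 2:n) {
    denom <- bb[i] - aa[i] * cp[i - 1]
    cp[i] <- cc[i] / denom
    dp[i] <- (op$s[i] - aa[i] * dp[i - 1]) / denom
  }
  P <- numeric(n); P[n] <- dp[n]
  for (i in (n - 1):1) P[i] <- dp[i] - cp[i] * P[i + 1]
  if (any(P < 0)) stop("non-positive stationary solution: discretization error")
  J <- .fp_face_flux(op, P, problem)
  mean(J) # constant across faces up to round-off
}

# MFPT by the classical double-integral formula for a 1-D diffusion with
# reflecting boundary at 0 and absorbing boundary at N:
#   tau(m0) = int_{m0}^N dm a^2 e^{beta F(m)} / D(m) int_0^m dz e^{-beta F(z)}
.fp_mfpt_quadrature <- function(problem, m_start, n_quad = 8192) {
  N <- problem$N
  m <- seq(0, N, length.out = n_quad + 1)
  bF <- problem$beta * problem$F(m)
  bF <- bF - min(bF) # gauge shift for conditioning
  inner <- pracma::cumtrapz(m, exp(-bF))[, 1]
  outer_int <- problem$a^2 * exp(bF) / problem$D(m) * inner
  keep <- m >= m_start
  pracma::trapz(m[keep], outer_int[keep])
}

#' Mean first-passage (escape) time of the threading coordinate
#'
#' The mean time for the chain to reach complete translocation (`m = N`,
#' absorbing) starting from `m_start`, with a reflecting inlet.  Computed two
#' ways: (i) the classical double-integral quadrature formula for a 1-D
#' diffusion, and (ii) the first moment of the first-passage density
#' simulated with [fp_evolve()] (time integral of the survival probability,
#' with an exponential tail correction).  Both are returned together with
#' their relative difference; a difference beyond `tol` signals that the
#' default resolution is insufficient.
#'
#' @param problem a [drift_diffusion_problem()] with reflecting inlet and
#'   absorbing outlet.
#' @param m_start starting coordinate.
#' @param n_grid grid for the PDE route.
#' @param tol acceptable relative difference between the two routes.
#' @param check error if the two routes disagree beyond `tol`?
#' @return list with `tau` (quadrature value), `tau_pde`,
#'   `relative_difference`.
#' @export
mean_first_passage_time <- function(problem, m_start = 0, n_grid = 512,
                                    tol = 0.01, check = TRUE) {
  stopifnot(inherits(problem, "drift_diffusion_problem"))
  if (problem$boundary_at_0 != "reflecting" ||
      problem$boundary_at_N != "absorbing")
    stop("MFPT needs reflecting at 0 and absorbing at N")
  tau_q <- .fp_mfpt_quadrature(problem, m_start)
  sol <- fp_evolve(problem, t_final = 8 * tau_q, n_grid = n_grid,
                   dt = tau_q / 1500, n_store = 2, m_start = m_start)
  S <- sol$survival; tg <- sol$step_times
  tau_pde <- pracma::trapz(tg, S)
  # exponential tail beyond t_final: S ~ S_end e^{-lambda t}
  nlast <- length(S)
  win <- max(2, nlast - 200):nlast
  lam <- -unname(stats::coef(stats::lm.fit(cbind(1, tg[win]),
                                           log(pmax(S[win], 1e-300))))[2])
  if (is.finite(lam) && lam > 0) tau_pde <- tau_pde + S[nlast] / lam
  rel <- abs(tau_pde - tau_q) / tau_q
  if (check && rel > tol)
    stop("MFPT routes disagree by ", format(rel),
         "; increase n_grid or lower dt")
  list(tau = tau_q, tau_pde = tau_pde, relative_difference = rel)
}

#' First-passage-time density of complete translocation
#'
#' `-dS/dt` evaluated on a requested time grid, where `S(t)` is the survival
#' probability of the evolving density.  Integrates to the eventual
#' absorption probability (1 for an absorbing outlet).
#'
#' @param problem a [drift_diffusion_problem()] (reflecting inlet, absorbing
#'   outlet).
#' @param m_start starting coordinate.
#' @param time_grid times at which to report the density.
#' @param n_grid spatial resolution.
#' @return data.frame with columns `time`, `density`.
#' @export
first_passage_histogram <- function(problem, m_start = 0, time_grid,
                                    n_grid = 512) {
  stopifnot(inherits(problem, "drift_diffusion_problem"))
  if (problem$boundary_at_0 != "reflecting" ||
      problem$boundary_at_N != "absorbing")
    stop("first passage needs reflecting at 0 and absorbing at N")
  t_final <- max(time_grid)
  dt <- min(diff(sort(unique(c(0, time_grid)))), t_final / 2000)
  sol <- fp_evolve(problem, t_final = t_final, n_grid = n_grid, dt = dt,
                   n_store = 2, m_start = m_start)
  S <- sol$survival; tg <- sol$step_times
  dens_steps <- -diff(S) / diff(tg)
  mid <- (tg[-1] + tg[-length(tg)]) / 2
  dens <- stats::approx(mid, dens_steps, xout = time_grid, rule = 2)$y
  if (any(dens < -1e-8 * max(abs(dens))))
    stop("negative first-passage density beyond tolerance")
  data.frame(time = time_grid, density = pmax(dens, 0))
}
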