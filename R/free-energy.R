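#' Chain-statistics exponents for the two sides of the membrane
#'
#' The partition sum of a chain of `m` monomers tethered at an impenetrable
#' wall scales as `Z_m ~ m^(gamma - 1)`.  The partition exponent `gamma` is
#' 0.5 for ideal (Gaussian) chains, approximately 0.69 for self-avoiding
#' chains and 1 for rod-like chains; the cis and trans sides may carry
#' different values.
#'
#' @param preset one of `"gaussian"`, `"self_avoiding"`, `"rodlike"`,
#'   `"custom"`.  Presets set both exponents to the standard value.
#' @param gamma1,gamma2 exponents for the cis and trans side; required (in
#'   `(0, 1]`) when `preset = "custom"`, ignored otherwise.
#' @return an object of class `chain_statistics` with fields `gamma1`,
#'   `gamma2`, `preset`.
#' @examples
#' chain_statistics("gaussian")
#' chain_statistics("custom", gamma1 = 0.5, gamma2 = 0.69)
#' @export
chain_statistics <- function(preset = c("gaussian", "self_avoiding",
                                        "rodlike", "custom"),
                             gamma1 = NULL, gamma2 = NULL) {
  preset <- match.arg(preset)
  std <- c(gaussian = 0.5, self_avoiding = 0.69, rodlike = 1.0)
  if (preset == "custom") {
    if (is.null(gamma1) || is.null(gamma2))
      stop("custom chain statistics require both gamma1 and gamma2")
  } else {
    gamma1 <- gamma2 <- unname(std[preset])
  }
  for (g in c(gamma1, gamma2))
    if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0 || g > 1)
      stop("chain-statistics exponents must satisfy 0 < gamma <= 1, got ", g)
  structure(list(gamma1 = gamma1, gamma2 = gamma2, preset = preset),
            class = "chain_statistics")
}

#' @export
print.chain_statistics <- function(x, ...) {
  cat(sprintf("<chain_statistics> preset=%s gamma1=%g gamma2=%g\n",
              x$preset, x$gamma1, x$gamma2))
  invisible(x)
}

#' Free-energy barrier for polymer translocation
#'
#' Defines the free energy of a partially translocated chain as a function of
#' the threading coordinate `m` (number of monomers on the trans side):
#' `beta F(m) = (1 - gamma1) ln(N - m) + (1 - gamma2) ln(m) + m beta dmu`,
#' the entropic cost of tethering both sub-chains at the pore plus a linear
#' chemical-potential term.  With `gamma1 = gamma2 = gamma` this is
#' `F(m) = (1 - gamma) kT ln[m (N - m)] + m dmu`.
#'
#' Sign convention: `delta_mu = mu_cis - mu_trans`; negative `delta_mu`
#' lowers the free energy at large `m` and therefore favours translocation.
#'
#' @param N total number of segments (integer, >= 2).
#' @param delta_mu chemical-potential difference per segment (energy units).
#' @param kT thermal energy (> 0); `beta = 1/kT`.
#' @param chain_stats a [chain_statistics()] object.
#' @return object of class `translocation_barrier`.
#' @export
translocation_barrier <- function(N, delta_mu = 0, kT = 1,
                                  chain_stats = chain_statistics("gaussian")) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != floor(N))
    stop("N must be an integer >= 2")
  if (!is.numeric(kT) || kT <= 0) stop("kT must be positive")
  stopifnot(inherits(chain_stats, "chain_statistics"))
  structure(list(N = as.numeric(N), delta_mu = delta_mu, kT = kT,
                 chain_stats = chain_stats),
            class = "translocation_barrier")
}

#' @export
print.translocation_barrier <- function(x, ...) {
  cat(sprintf(
    "<translocation_barrier> N=%g delta_mu=%g kT=%g gamma1=%g gamma2=%g\n",
    x$N, x$delta_mu, x$kT, x$chain_stats$gamma1, x$chain_stats$gamma2))
  invisible(x)
}

#' Entropic + chemical-potential free energy of a partially threaded chain
#'
#' Evaluates `F(m) = kT[(1 - gamma1) ln(N - m) + (1 - gamma2) ln(m)]
#' + m delta_mu`.  `F` diverges logarithmically at the endpoints for
#' `gamma < 1`; evaluation is therefore restricted to `[delta, N - delta]`
#' (default `delta = 1e-6 N`).  With `clamp = TRUE` arguments inside `[0, N]`
#' but outside that window are clamped to it; arguments outside `[0, N]` are
#' always an error.
#'
#' @param m threading coordinate, vectorised; treated as continuous.
#' @param barrier a [translocation_barrier()].
#' @param clamp clamp `m` into `[delta, N - delta]`? If `FALSE`, values
#'   outside the window are an error.
#' @param delta endpoint guard, default `1e-6 * N`.
#' @return free energy (same units as `kT`), vectorised over `m`.
#' @examples
#' b <- translocation_barrier(N = 4)
#' entropic_free_energy(2, b)  # 0.5 * log(4)
#' @export
entropic_free_energy <- function(m, barrier, clamp = TRUE,
                                 delta = 1e-6 * barrier$N) {
  stopifnot(inherits(barrier, "translocation_barrier"))
  N <- barrier$N
  if (any(!is.finite(m)) || any(m < 0) || any(m > N))
    stop("m must lie in [0, N]")
  lo <- delta; hi <- N - delta
  if (clamp) {
    m <- pmin(pmax(m, lo), hi)
  } else if (any(m < lo) || any(m > hi)) {
    stop("m outside the evaluation window [delta, N - delta]; ",
         "use clamp = TRUE or a smaller delta")
  }
  g1 <- barrier$chain_stats$gamma1
  g2 <- barrier$chain_stats$gamma2
  barrier$kT * ((1 - g1) * log(N - m) + (1 - g2) * log(m)) +
    m * barrier$delta_mu
}

#' Interior maximum of the translocation barrier
#'
#' Locates the top of the free-energy barrier by root-finding on
#' `dF/dm = kT[(1 - g2)/m - (1 - g1)/(N - m)] + delta_mu`, which is strictly
#' decreasing in `m`, so any sign change brackets the unique interior
#' maximum.  With `gamma1 = gamma2 = 1` the free energy is linear in `m` and
#' no interior maximum exists; an error of class
#' `translokit_no_interior_maximum` is signalled.
#'
#' @param barrier a [translocation_barrier()].
#' @param tol root-finder tolerance on `m`.
#' @return list with `m_star` (location) and `F_star` (height).
#' @export
barrier_maximum <- function(barrier, tol = 1e-10) {
  stopifnot(inherits(barrier, "translocation_barrier"))
  g1 <- barrier$chain_stats$gamma1
  g2 <- barrier$chain_stats$gamma2
  N <- barrier$N; kT <- barrier$kT; dmu <- barrier$delta_mu
  if (g1 == 1 && g2 == 1)
    stop(structure(class = c("translokit_no_interior_maximum",
                             "error", "condition"),
                   list(message = "no interior maximum, F is linear in m",
                        call = sys.call(-1))))
  dF <- function(m) kT * ((1 - g2) / m - (1 - g1) / (N - m)) + dmu
  eps <- 1e-12 * N
  lo <- eps; hi <- N - eps
  if (dF(lo) <= 0 || dF(hi) >= 0) {
    # monotone over (0, N): supremum sits at an endpoint, not interior
    stop(structure(class = c("translokit_no_interior_maximum",
                             "error", "condition"),
                   list(message = "no interior maximum on (0, N)",
                        call = sys.call(-1))))
  }
  m_star <- stats::uniroot(dF, lower = lo, upper = hi, tol = tol)$root
  list(m_star = m_star,
       F_star = entropic_free_energy(m_star, barrier, clamp = FALSE,
                                     delta = eps))
}

#' Least-squares parabolic surrogate of the barrier
#'
#' Samples `F(m)` on a window well inside `(0, N)` and fits the concave
#' parabola `F(m) = -b1 m^2 + b2 m + b3` (with `b1 > 0` enforced) that feeds
#' the closed-form flux.  The default window `[0.1 N, 0.9 N]` avoids the
#' logarithmic endpoint singularities while covering the bulk of the barrier.
#'
#' @param barrier a [translocation_barrier()], or a plain function `F(m)`
#'   (then `m_lo`/`m_hi` must be given explicitly).
#' @param m_lo,m_hi fit window, `0 < m_lo < m_hi < N`.
#' @param n_samples number of uniform samples (>= 3).
#' @return a [parabolic_barrier()] with attribute `residual_norm` (L2 norm of
#'   fit residuals) and `window`.
#' @export
fit_parabola <- function(barrier, m_lo = 0.1 * barrier$N,
                         m_hi = 0.9 * barrier$N, n_samples = 81) {
  if (is.function(barrier)) {
    if (!(is.numeric(m_lo) && is.numeric(m_hi) && m_lo < m_hi))
      stop("fit window must satisfy m_lo < m_hi")
    if (n_samples < 3)
      stop("n_samples must be >= 3 (parabola has 3 coefficients)")
    m <- seq(m_lo, m_hi, length.out = n_samples)
    Fm <- barrier(m)
  } else {
  stopifnot(inherits(barrier, "translocation_barrier"))
  N <- barrier$N
  if (!(m_lo > 0 && m_hi < N && m_lo < m_hi))
    stop("fit window must satisfy 0 < m_lo < m_hi < N")
  if (n_samples < 3) stop("n_samples must be >= 3 (parabola has 3 coefficients)")
  m <- seq(m_lo, m_hi, length.out = n_samples)
  Fm <- entropic_free_energy(m, barrier, clamp = FALSE, delta = 0)
  }
  co <- stats::lm.fit(cbind(`m2` = -m^2, m = m, const = 1), Fm)$coefficients
  if (!is.finite(co[1]) || co[1] <= 0)
    stop("barrier is not concave on the requested window (fitted b1 <= 0)")
  pb <- parabolic_barrier(b1 = unname(co[1]), b2 = unname(co[2]),
                          b3 = unname(co[3]))
  fitted <- -pb$b1 * m^2 + pb$b2 * m + pb$b3
  attr(pb, "residual_norm") <- sqrt(sum((Fm - fitted)^2))
  attr(pb, "window") <- c(m_lo, m_hi)
  pb
}

#' Free-energy difference of the parabolic surrogate
#'
#' `F(m) - F(0) = -b1 m^2 + b2 m`; the gauge constant `b3` drops out, and no
#' observable of the toolkit depends on it.
#'
#' @param m threading coordinate (vectorised).
#' @param pb a [parabolic_barrier()].
#' @export
parabolic_difference <- function(m, pb) {
  stopifnot(inherits(pb, "parabolic_barrier"))
  -pb$b1 * m^2 + pb$b2 * m
}

#' Sample the barrier profile
#'
#' @param barrier a [translocation_barrier()].
#' @param m optional evaluation points; default 401 points across the
#'   clamped domain.
#' @return data.frame with columns `m`, `F`.
#' @export
barrier_profile <- function(barrier, m = NULL) {
  stopifnot(inherits(barrier, "translocation_barrier"))
  if (is.null(m)) {
    d <- 1e-6 * barrier$N
    m <- seq(d, barrier$N - d, length.out = 401)
  }
  data.frame(m = m, F = entropic_free_energy(m, barrier))
}
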