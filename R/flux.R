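#' Linear friction model for the threading chain
#'
#' Total friction felt by the chain when `m` monomers have translocated:
#' `C(m) = c1 m + c2`, with `c1` the friction per monomer in the pore and
#' `c2` an offset.  Positivity of `C` on the domain is checked when the model
#' is combined with a chain length in [flux_inputs()].
#'
#' @param c1 friction per monomer (>= 0).
#' @param c2 offset friction.
#' @export
friction_model <- function(c1, c2) {
  if (!is.numeric(c1) || c1 < 0) stop("c1 must be >= 0")
  structure(list(c1 = c1, c2 = c2), class = "friction_model")
}

#' Parabolic barrier surrogate
#'
#' Concave parabola `F(m) = -b1 m^2 + b2 m + b3` standing in for the
#' entropic barrier in the closed-form flux.  `b1 > 0` is required for the
#' closed form; `b1 = 0` (no curvature) is accepted but served by quadrature
#' only.  `b3` is a gauge constant: only `F(m) - F(0)` enters any observable.
#'
#' @param b1 curvature (>= 0; > 0 for the closed form).
#' @param b2 linear coefficient.
#' @param b3 offset (gauge only).
#' @export
parabolic_barrier <- function(b1, b2, b3 = 0) {
  if (!is.numeric(b1) || !is.finite(b1) || b1 < 0)
    stop("b1 must be >= 0 (concave barrier)")
  structure(list(b1 = b1, b2 = b2, b3 = b3), class = "parabolic_barrier")
}

#' Inputs for the steady-state flux
#'
#' Bundles the parabolic barrier, the linear friction model, the monomer size
#' `a`, the chain length `N`, the inverse thermal energy `beta` and the inlet
#' probability `P0` (probability that the last monomer sits at the pore
#' inlet).  The steady-state flux is `J = P0 / f(N)` with
#' `f(N) = a^2 beta * integral_0^N C(m) exp(beta [F(m) - F(0)]) dm`.
#'
#' @param pb a [parabolic_barrier()].
#' @param friction a [friction_model()].
#' @param a monomer size (> 0); the chain length is `l = N a`.
#' @param N segment count (>= 1).
#' @param beta inverse thermal energy (> 0).
#' @param P0 inlet probability in `[0, 1]`.
#' @export
flux_inputs <- function(pb, friction, a = 1, N, beta = 1, P0 = 1) {
  stopifnot(inherits(pb, "parabolic_barrier"),
            inherits(friction, "friction_model"))
  if (!is.numeric(a) || a <= 0) stop("a must be > 0")
  if (!is.numeric(N) || N < 1) stop("N must be >= 1")
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  if (!is.numeric(P0) || P0 < 0 || P0 > 1) stop("P0 must lie in [0, 1]")
  for (m in c(0, N))
    if (friction$c1 * m + friction$c2 <= 0)
      stop("friction C(m) = c1 m + c2 must be positive on [0, N]")
  structure(list(pb = pb, friction = friction, a = a, N = N, beta = beta,
                 P0 = P0),
            class = "flux_inputs")
}

# exponent of the barrier factor: phi(m) = beta (-b1 m^2 + b2 m)
.flux_phi <- function(m, inputs) {
  inputs$beta * (-inputs$pb$b1 * m^2 + inputs$pb$b2 * m)
}

#' Integrand of the barrier integral
#'
#' `C(m) exp(beta [F(m) - F(0)]) = (c1 m + c2) exp(beta (-b1 m^2 + b2 m))`.
#' For sharp rising barriers the exponent overflows a double; the log of the
#' integrand is always finite and can be requested with `log = TRUE`
#' (overflow in the linear-scale value is signalled with a warning).
#'
#' @param m evaluation points in `[0, N]` (vectorised).
#' @param inputs a [flux_inputs()].
#' @param log return `log` of the integrand?
#' @export
barrier_integrand <- function(m, inputs, log = FALSE) {
  stopifnot(inherits(inputs, "flux_inputs"))
  if (any(m < 0) || any(m > inputs$N)) stop("m must lie in [0, N]")
  lg <- log(inputs$friction$c1 * m + inputs$friction$c2) +
    .flux_phi(m, inputs)
  if (log) return(lg)
  out <- exp(lg)
  if (any(is.infinite(out)))
    warning("barrier integrand overflows double precision; use log = TRUE")
  out
}

# ---- stable closed form ----------------------------------------------------

# log(1 - e^d) for d <= 0, accurate for d near 0 and for d -> -Inf
.log1mexp <- function(d) {
  if (d >= 0) return(-Inf)
  if (d < -log(2)) log1p(-exp(d)) else log(-expm1(d))
}

# scaled complementary error function e^{s^2} erfc(s), s >= 0.  pracma's
# version evaluates exp(s^2) * erfc(s) directly and degenerates to NaN once
# erfc underflows (s > ~27); switch to the asymptotic series there, whose
# truncation error is far below double precision at that point.
.erfcx <- function(s) {
  out <- numeric(length(s))
  small <- s <= 25
  if (any(small)) out[small] <- pracma::erfcx(s[small])
  if (any(!small)) {
    z <- 1 / (2 * s[!small]^2)
    acc <- 1; term <- rep(1, sum(!small))
    for (k in 1:10) {
      term <- term * (-(2 * k - 1)) * z
      acc <- acc + term
    }
    out[!small] <- acc / (s[!small] * sqrt(pi))
  }
  out
}

# remainder R(s) = 1 - sqrt(pi) s erfcx(s), s >= 0.  Direct evaluation loses
# ~log10(2 s^2) digits to cancellation; beyond s = 25 the asymptotic series
# R ~ 1/(2 s^2) - 3/(4 s^4) + 15/(8 s^6) - ... is accurate to ~1e-16 relative.
.erfcx_remainder <- function(s) {
  out <- numeric(length(s))
  small <- s <= 25
  if (any(small))
    out[small] <- 1 - sqrt(pi) * s[small] * .erfcx(s[small])
  if (any(!small)) {
    z <- 1 / (s[!small]^2)
    acc <- 0
    term <- rep(0.5, sum(!small)) * z          # (2k-1)!!/2^k s^-2k, k = 1
    for (k in 1:10) {
      acc <- acc + term
      term <- term * (-(2 * k + 1) / 2) * z
    }
    out[!small] <- acc
  }
  out
}

# log of G = int_0^N exp(phi) dm and H = int_0^N m exp(phi) dm for
# phi = beta(-b1 m^2 + b2 m), b1 > 0, restricted to b2 <= b1 N (barrier peak
# in the left half or outside on the left).  Three regimes keep every
# combination cancellation-free:
#   b2 <= 0  : pure decay, erfcx + remainder form;
#   0 < b2   : interior peak at p = b2/(2 b1) <= N/2, positive-sum form with
#              the (possibly huge) factor e^{beta b2^2/(4 b1)} kept in logs.
.flux_GH_left <- function(b1, b2, beta, N) {
  sb <- sqrt(beta * b1)
  T_ <- sb * N
  pref_G_log <- log(sqrt(pi) / (2 * sb))
  phiN <- beta * N * (b2 - b1 * N)   # <= 0 in this regime
  if (b2 <= 0) {
    s0 <- -sqrt(beta) * b2 / (2 * sqrt(b1))  # >= 0
    sN <- s0 + T_
    le0 <- log(.erfcx(s0))
    leN <- log(.erfcx(sN))
    logG <- pref_G_log + le0 + .log1mexp(phiN + leN - le0)
    r0 <- .erfcx_remainder(s0)
    innerN <- .erfcx_remainder(sN) + sqrt(pi) * T_ * .erfcx(sN)
    d <- phiN + log(innerN) - log(r0)
    logH <- -log(2 * beta * b1) + log(r0) + .log1mexp(d)
  } else {
    p <- b2 / (2 * b1)
    A <- beta * b1 * p^2
    sN <- sb * (N - p)
    logGbar <- A + log(pracma::erf(sb * p) + pracma::erf(sN))
    logG <- pref_G_log + logGbar
    # H = (1 - e^{phiN})/(2 beta b1) + p * G, all positive
    t1 <- -log(2 * beta * b1) + .log1mexp(phiN)
    t2 <- log(p) + logG
    mx <- max(t1, t2)
    logH <- mx + log(exp(t1 - mx) + exp(t2 - mx))
  }
  list(logG = logG, logH = logH)
}

# log f(N) via the closed form, stable for arbitrary barrier sharpness.
# Barriers rising towards m = N (b2 > b1 N) are reduced to the left-peak
# regime by the reflection m -> N - m, which multiplies the integrand by
# e^{phi(N)} and maps (c1, c2, b2) -> (-c1, c1 N + c2, 2 b1 N - b2).
.flux_logf_closed <- function(inputs) {
  b1 <- inputs$pb$b1; b2 <- inputs$pb$b2
  c1 <- inputs$friction$c1; c2 <- inputs$friction$c2
  beta <- inputs$beta; N <- inputs$N
  if (b1 <= 0)
    stop("closed form requires b1 > 0; use quadrature for b1 = 0")
  base <- log(inputs$a^2 * beta)
  if (b2 <= b1 * N) {
    gh <- .flux_GH_left(b1, b2, beta, N)
    terms <- c(if (c2 > 0) log(c2) + gh$logG,
               if (c1 > 0) log(c1) + gh$logH)
    mx <- max(terms)
    base + mx + log(sum(exp(terms - mx)))
  } else {
    phiN <- beta * N * (b2 - b1 * N)  # > 0
    gh <- .flux_GH_left(b1, 2 * b1 * N - b2, beta, N)
    lpos <- log(c1 * N + c2) + gh$logG
    if (c1 > 0) {
      lneg <- log(c1) + gh$logH
      base + phiN + lpos + .log1mexp(lneg - lpos)
    } else {
      base + phiN + lpos
    }
  }
}

#' Barrier integral by adaptive quadrature
#'
#' Ground-truth evaluation of
#' `f(N) = a^2 beta * integral_0^N C(m) exp(beta [F(m) - F(0)]) dm` by
#' adaptive quadrature, after factoring out the peak value of the exponent so
#' that arbitrarily sharp barriers stay representable.  The interval is split
#' at the barrier peak so each piece is monotone.
#'
#' @param inputs a [flux_inputs()].
#' @param rel_tol relative tolerance of the quadrature.
#' @param log return `log f(N)` instead of `f(N)`?
#' @export
f_of_N_quadrature <- function(inputs, rel_tol = 1e-10, log = FALSE) {
  stopifnot(inherits(inputs, "flux_inputs"))
  b1 <- inputs$pb$b1; b2 <- inputs$pb$b2; N <- inputs$N
  pts <- c(0, N)
  if (b1 > 0) {
    p <- b2 / (2 * b1)
    if (p > 0 && p < N) pts <- c(0, p, N)
  }
  phi_star <- max(.flux_phi(pts, inputs))
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    q <- stats::integrate(
      function(m) exp(barrier_integrand(m, inputs, log = TRUE) - phi_star),
      lower = pts[i], upper = pts[i + 1],
      rel.tol = rel_tol, abs.tol = 0, subdivisions = 500L)
    if (q$message != "OK")
      stop("quadrature did not converge: ", q$message,
           " (piece [", pts[i], ", ", pts[i + 1], "])")
    total <- total + q$value
  }
  lf <- log(inputs$a^2 * inputs$beta) + phi_star + base::log(total)
  if (log) lf else exp(lf)
}

#' Closed-form antiderivative of the barrier integrand
#'
#' The antiderivative of `(c1 m + c2) exp(beta(-b1 m^2 + b2 m))`, derived by
#' splitting `m e^phi` into a total derivative plus a Gaussian integral:
#' `I(m) = -(c1 / (2 beta b1)) e^{beta(-b1 m^2 + b2 m)} +
#'  ((2 c2 b1 + c1 b2) / (4 b1^{3/2})) sqrt(pi/beta) e^{beta b2^2/(4 b1)}
#'  erf(sqrt(beta b1) m - sqrt(beta) b2 / (2 sqrt(b1)))`.
#' This direct form is exact but overflows for very sharp barriers
#' (`beta b2^2 / (4 b1)` large); [f_of_N_closed_form()] evaluates the
#' difference `I(N) - I(0)` in log space instead and should be preferred for
#' observables.
#'
#' @param m evaluation point(s).
#' @param inputs a [flux_inputs()]; requires `b1 > 0`.
#' @export
I_closed_form <- function(m, inputs) {
  stopifnot(inherits(inputs, "flux_inputs"))
  b1 <- inputs$pb$b1; b2 <- inputs$pb$b2
  c1 <- inputs$friction$c1; c2 <- inputs$friction$c2
  beta <- inputs$beta
  if (b1 <= 0) stop("closed form requires b1 > 0; use quadrature")
  -(c1 / (2 * beta * b1)) * exp(.flux_phi(m, inputs)) +
    ((2 * c2 * b1 + c1 * b2) / (4 * b1^1.5)) * sqrt(pi / beta) *
      exp(beta * b2^2 / (4 * b1)) *
      pracma::erf(sqrt(beta * b1) * m - sqrt(beta) * b2 / (2 * sqrt(b1)))
}

#' Barrier integral in closed form
#'
#' `f(N) = a^2 beta [I(N) - I(0)]`, evaluated through a numerically stable
#' log-space rearrangement (scaled complementary error function for decaying
#' exponents, log-sum-exp around the peak factor for interior maxima, and a
#' reflection `m -> N - m` for barriers rising towards `N`), so the result is
#' accurate for arbitrarily sharp barriers where the textbook form overflows.
#'
#' @param inputs a [flux_inputs()]; requires `b1 > 0`.
#' @param log return `log f(N)`?
#' @export
f_of_N_closed_form <- function(inputs, log = FALSE) {
  stopifnot(inherits(inputs, "flux_inputs"))
  lf <- .flux_logf_closed(inputs)
  if (log) lf else exp(lf)
}

#' Steady-state polymer flux through the pore
#'
#' `J = P0 / f(N)`.  `method = "auto"` uses the closed form whenever the
#' barrier has curvature (`b1 > 0`) and falls back to quadrature otherwise.
#' Whenever both routes are available the result records their relative
#' disagreement; a disagreement beyond `consistency_tol` aborts, protecting
#' against any defect in the reconstructed antiderivative.
#'
#' @param inputs a [flux_inputs()].
#' @param method `"auto"`, `"closed_form"` or `"quadrature"`.
#' @param p0_map optional fixed-point hook `function(J) -> P0` for inlet
#'   statistics that depend on the flux; `NULL` (the default) keeps `P0`
#'   independent of `J`.
#' @param consistency_tol closed-form vs quadrature gate (relative).
#' @return object of class `flux_result`: fields `J`, `fN`, `log_fN`,
#'   `method`, `relative_disagreement`, `inputs`.
#' @export
flux <- function(inputs, method = c("auto", "closed_form", "quadrature"),
                 p0_map = NULL, consistency_tol = 1e-6) {
  stopifnot(inherits(inputs, "flux_inputs"))
  method <- match.arg(method)
  has_closed <- inputs$pb$b1 > 0
  if (method == "closed_form" && !has_closed)
    stop("closed form unavailable for b1 = 0")
  use <- if (method == "auto") {
    if (has_closed) "closed_form" else "quadrature"
  } else method
  log_q <- f_of_N_quadrature(inputs, log = TRUE)
  disagreement <- NA_real_
  if (has_closed) {
    log_cf <- .flux_logf_closed(inputs)
    disagreement <- abs(expm1(log_cf - log_q))
    if (use == "closed_form" && disagreement > consistency_tol)
      stop("closed form and quadrature disagree (relative ",
           format(disagreement), "); inputs outside the validated domain")
  }
  log_f <- if (use == "closed_form") log_cf else log_q
  if (!is.finite(log_f) || exp(log_f) <= 0)
    stop("internal error: f(N) must be positive and finite in log space")
  P0 <- inputs$P0
  if (!is.null(p0_map)) { # fixed-point iteration on P0(J)
    for (it in 1:100) {
      J <- P0 * exp(-log_f)
      P0_new <- p0_map(J)
      if (!is.numeric(P0_new) || P0_new < 0 || P0_new > 1)
        stop("p0_map must return a probability in [0, 1]")
      if (abs(P0_new - P0) < 1e-12) break
      P0 <- P0_new
    }
  }
  structure(list(J = P0 * exp(-log_f), fN = exp(log_f), log_fN = log_f,
                 P0 = P0, method = use,
                 relative_disagreement = disagreement, inputs = inputs),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> J=%.6g  f(N)=%.6g (log %.6g)  method=%s\n",
              x$J, x$fN, x$log_fN, x$method))
  if (is.finite(x$relative_disagreement))
    cat(sprintf("  closed-form vs quadrature relative disagreement: %.3g\n",
                x$relative_disagreement))
  invisible(x)
}
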