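#' Exact census of wall-tethered ideal-chain configurations
#'
#' Counts, exactly, the `m`-step +/-1 walks from the origin that never go
#' below it — the minimal lattice realisation of an ideal chain tethered at
#' an impenetrable wall, whose configuration count behaves as
#' `Z_m ~ 2^m m^(gamma - 1)` with partition exponent `gamma = 1/2`.  The
#' dynamic programme accumulates arbitrary-precision integers (counts exceed
#' 2^4000 at the largest `m`); the result equals the central binomial
#' coefficient `choose(m, floor(m/2))`.
#'
#' @param m number of steps, integer in `[1, 4096]`.
#' @return object of class `walk_count`: `m`, `count` (exact double when it
#'   fits 53 bits, otherwise `NA`), `count_string` (exact decimal),
#'   `log_count` (natural log, accurate to ~1e-15 relative).
#' @examples
#' count_halfspace_walks(4)$count  # 6: the walks {++++...} etc.
#' @export
count_halfspace_walks <- function(m) {
  if (length(m) != 1L || !is.finite(m) || m < 1 || m > 4096 || m != floor(m))
    stop("m must be a single integer in [1, 4096]")
  res <- .cpp_halfspace_walk_count(as.integer(m))
  structure(list(m = as.integer(m), count = res$count,
                 count_string = res$count_string,
                 log_count = res$log_count, log2_count = res$log2_count),
            class = "walk_count")
}

#' @export
print.walk_count <- function(x, ...) {
  cat(sprintf("<walk_count> m=%d count=%s (log %.6f)\n", x$m,
              x$count_string, x$log_count))
  invisible(x)
}

#' Power-law fit on log-log axes
#'
#' Ordinary least squares of `log y` on `log x`, with a seeded bootstrap
#' (200 resamples) standard error on the exponent.
#'
#' @param x,y positive vectors of equal length (>= 3).
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return object of class `power_law_fit`: `exponent`, `intercept`
#'   (`log`-scale), `stderr`, `x_range`, `n_points`.
#' @export
fit_power_law <- function(x, y, n_boot = 200, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points for a power-law fit")
  if (any(x <= 0) || any(y <= 0)) stop("power-law fit needs positive data")
  lx <- log(x); ly <- log(y)
  co <- stats::coef(stats::lm.fit(cbind(1, lx), ly))
  boot <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(x), replace = TRUE)
      if (length(unique(lx[idx])) < 2) return(NA_real_)
      stats::coef(stats::lm.fit(cbind(1, lx[idx]), ly[idx]))[2]
    }, numeric(1))
  })
  structure(list(exponent = unname(co[2]), intercept = unname(co[1]),
                 stderr = stats::sd(boot, na.rm = TRUE),
                 x_range = range(x), n_points = length(x)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> exponent=%.4f (se %.4f) over x in [%g, %g], n=%d\n",
    x$exponent, x$stderr, x$x_range[1], x$x_range[2], x$n_points))
  invisible(x)
}

#' Estimate the partition exponent gamma from configuration counts
#'
#' Fits `log(Z_m / 2^m)` against `log m` and reports
#' `gamma = 1 + slope`, since `Z_m ~ 2^m m^(gamma - 1)` for the half-space
#' walk census.  Synthetic counts can be supplied through `log_counts` (per
#' `m`, natural log, including the `mu^m` growth factor with `log_mu` the
#' per-step factor to remove).
#'
#' @param m_values walk lengths; must span at least 1.5 decades.
#' @param log_counts optional log counts; `NULL` uses the exact census.
#' @param log_mu log of the per-step growth factor to divide out
#'   (default `log(2)` for the +/-1 walk).
#' @return a [fit_power_law()] result with `exponent` replaced by `gamma`.
#' @export
estimate_gamma <- function(m_values, log_counts = NULL, log_mu = log(2)) {
  m_values <- sort(unique(as.integer(m_values)))
  if (log10(max(m_values) / min(m_values)) < 1.5)
    stop("m_values must span at least 1.5 decades for a stable fit")
  if (is.null(log_counts))
    log_counts <- vapply(m_values,
                         function(m) count_halfspace_walks(m)$log_count,
                         numeric(1))
  if (length(log_counts) != length(m_values))
    stop("log_counts must match m_values")
  resid <- log_counts - m_values * log_mu
  fit <- fit_power_law(m_values, exp(resid - max(resid)))
  fit$gamma <- 1 + fit$exponent
  fit
}

#' Estimate the Flory exponent by pivot sampling of self-avoiding walks
#'
#' Samples lattice self-avoiding walks with the pivot algorithm (global
#' lattice-symmetry moves, thermalised, thinned) at each chain length, and
#' fits the mean squared end-to-end distance against `N` on log-log axes;
#' `nu = slope / 2`.  Known values: `nu = 3/4` in 2-D (exact),
#' `nu ~ 0.588` in 3-D.
#'
#' @param dimension 2 or 3.
#' @param N_values chain lengths; must span at least a factor 8.
#' @param samples_per_N samples per chain length.
#' @param seed RNG seed.
#' @param thin accepted pivots between samples.
#' @param n_therm accepted pivots discarded before sampling.
#' @return a [fit_power_law()] result with `nu = exponent/2` added, plus
#'   `data` (per-N mean R^2) and `acceptance`.
#' @export
estimate_flory_nu <- function(dimension = 3,
                              N_values = c(32, 64, 128, 256, 512),
                              samples_per_N = 2000, seed = 1L, thin = 4,
                              n_therm = 500) {
  N_values <- sort(unique(N_values))
  if (max(N_values) / min(N_values) < 8)
    stop("N_values must span at least a factor 8")
  mean_r2 <- numeric(length(N_values)); acc <- numeric(length(N_values))
  for (i in seq_along(N_values)) {
    res <- .cpp_saw_pivot_r2(as.integer(N_values[i]),
                             as.integer(samples_per_N),
                             as.integer(dimension), as.integer(thin),
                             as.integer(n_therm),
                             as.numeric(seed) * 1000 + i, 10000L)
    mean_r2[i] <- res$mean_r2
    acc[i] <- res$acceptance
  }
  fit <- fit_power_law(N_values, mean_r2)
  fit$nu <- fit$exponent / 2
  fit$data <- data.frame(N = N_values, mean_r2 = mean_r2, acceptance = acc)
  fit
}

#' Scaling of the mean translocation time with chain length
#'
#' Runs replicated Langevin translocation events per chain length and fits
#' the power law of the mean escape time versus `N`.  In
#' `"end_pulled_strong_force"` mode the constant force is applied to the
#' leading bead and the strong-force condition `F N^nu / kT >> 1` is
#' checked for every `N`; the expected exponent there is 2 (escape time
#' `~ N^2 / F`).  The `"unforced"` mode (expected `N^(2+nu)`) is provided
#' but is slow: unforced escapes are rare events, so it is intended for
#' long-running experiments at reduced `N`.
#'
#' @param mode `"end_pulled_strong_force"` or `"unforced"`.
#' @param N_values chain lengths.
#' @param force end force, reduced units (strong-force mode).
#' @param replicates events per `N`.
#' @param params a [langevin_params()].
#' @param pore a [membrane_pore()].
#' @param max_time per-event budget.
#' @param seed base seed.
#' @param min_success minimum successful events per cell (refused below).
#' @param nu Flory exponent used in the regime check.
#' @return a [fit_power_law()] of mean tau vs N, with `data` attached.
#' @export
measure_tau_scaling <- function(mode = c("end_pulled_strong_force",
                                         "unforced"),
                                N_values = c(16, 32, 64, 128), force = 10,
                                replicates = 200,
                                params = langevin_params(dt = 0.02),
                                pore = membrane_pore(), max_time = 1e5,
                                seed = 1L, min_success = 50, nu = 0.588) {
  mode <- match.arg(mode)
  N_values <- sort(unique(N_values))
  if (mode == "end_pulled_strong_force") {
    weakest <- force * min(N_values)^nu / params$kT
    if (weakest <= 5)
      stop("strong-force regime requires F N^nu / kT >> 1 for every N ",
           "(got ", format(weakest), " at the smallest N)")
    field <- driving_field("end_force", end_force_f = force)
  } else {
    field <- driving_field("none")
  }
  rows <- lapply(seq_along(N_values), function(i) {
    N <- N_values[i]
    poly <- bead_spring_polymer(N)
    taus <- vapply(seq_len(replicates), function(rep) {
      ev <- run_translocation(poly, pore, field, params,
                              max_time = max_time,
                              seed = as.numeric(seed) * 1e7 + i * 1e5 + rep)
      if (ev$success) ev$tau else NA_real_
    }, numeric(1))
    taus <- taus[!is.na(taus)]
    if (length(taus) < min_success)
      stop("only ", length(taus), " successful events at N = ", N,
           "; refusing the fit")
    data.frame(N = N, mean_tau = mean(taus), sd_tau = stats::sd(taus),
               n_success = length(taus))
  })
  dat <- do.call(rbind, rows)
  fit <- fit_power_law(dat$N, dat$mean_tau)
  fit$data <- dat
  fit
}
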