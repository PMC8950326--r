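# Configuration, result serialisation and figure generation: the plumbing
# that ties the engines together and backs the translokit command line
# (inst/cli/translokit.R).

.engine_schemas <- function() {
  num <- function(lo = -Inf, hi = Inf, msg = NULL)
    list(check = function(v) is.numeric(v) && all(is.finite(v)) &&
           all(v >= lo) && all(v <= hi),
         msg = if (is.null(msg)) sprintf("numeric in [%g, %g]", lo, hi)
               else msg)
  str1 <- function(choices)
    list(check = function(v) is.character(v) && length(v) == 1 &&
           v %in% choices,
         msg = paste("one of", paste(choices, collapse = ", ")))
  list(
    barrier = list(
      required = c("N"),
      keys = list(
        N = num(2, Inf), kT = num(1e-300, Inf), delta_mu = num(),
        preset = str1(c("gaussian", "self_avoiding", "rodlike", "custom")),
        gamma1 = num(1e-12, 1), gamma2 = num(1e-12, 1),
        n_points = num(2, Inf))),
    flux = list(
      required = c("N", "b1", "b2", "c1", "c2"),
      keys = list(
        N = num(1, Inf),
        b1 = list(check = function(v) is.numeric(v) && is.finite(v) &&
                    v >= 0,
                  msg = "b1 must be >= 0 (the parabolic barrier requires b1 > 0 for the closed form)"),
        b2 = num(), b3 = num(), c1 = num(0, Inf), c2 = num(),
        beta = num(1e-300, Inf), a = num(1e-300, Inf), P0 = num(0, 1),
        method = str1(c("auto", "closed_form", "quadrature")))),
    fp = list(
      required = c("N", "t_final"),
      keys = list(
        N = num(1e-300, Inf), k0 = num(1e-300, Inf), beta = num(1e-300, Inf),
        a = num(1e-300, Inf), b1 = num(0, Inf), b2 = num(),
        boundary_at_0 = str1(c("reflecting", "fixed_value")),
        boundary_at_N = str1(c("absorbing", "reflecting")),
        P0 = num(0, 1), t_final = num(1e-300, Inf), n_grid = num(16, Inf),
        dt = num(1e-300, Inf), m_start = num(0, Inf), mfpt = list(
          check = function(v) is.logical(v) && length(v) == 1,
          msg = "logical"))),
    simulate = list(
      required = c("N"),
      keys = list(
        N = num(1, Inf), dt = num(1e-300, Inf), gamma = num(0, Inf),
        kT = num(0, Inf), mass = num(1e-300, Inf), bond_k = num(0, Inf),
        bond_length = num(1e-300, Inf),
        mode = str1(c("none", "electric_in_pore", "electric_uniform",
                      "end_force")),
        E = num(0, Inf), end_force_f = num(), q_eff = num(0, Inf),
        max_time = num(1e-300, Inf), events = num(1, Inf),
        pore_radius = num(1e-300, Inf), wall_thickness = num(1e-300, Inf))),
    scan = list(
      required = c("E_values", "N_values"),
      keys = list(
        E_values = num(0, Inf), N_values = num(1, Inf),
        reps = num(1, Inf), dt = num(1e-300, Inf), q_eff = num(0, Inf),
        max_time = num(1e-300, Inf),
        mode = str1(c("electric_in_pore", "electric_uniform")))),
    exponents = list(
      required = c("which"),
      keys = list(
        which = str1(c("gamma", "nu", "tau")),
        m_values = num(1, 4096), N_values = num(2, Inf),
        samples_per_N = num(10, Inf), dimension = num(2, 3),
        force = num(0, Inf), replicates = num(1, Inf),
        dt = num(1e-300, Inf), max_time = num(1e-300, Inf))),
    histogram = list(
      required = c("N"),
      keys = list(
        N = num(1, Inf), dt = num(1e-300, Inf),
        mode = str1(c("electric_in_pore", "electric_uniform",
                      "end_force")),
        E = num(0, Inf), end_force_f = num(), q_eff = num(0, Inf),
        n_events = num(100, Inf), max_time = num(1e-300, Inf)))
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration with top-level keys `engine` (one of
#' barrier, flux, fp, simulate, scan, exponents, histogram), `seed`,
#' optional `out`, and an engine-specific `parameters` block.  Validation is
#' exhaustive: every unknown key, missing required key and constraint
#' violation is reported in one error, with the list of valid keys.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return object of class `run_config`: `engine`, `parameters`, `seed`,
#'   `out`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      # YAML 1.1 resolves bare y/Y/n/N as booleans, which would silently
      # turn the chain-length key `N` into `FALSE`; keep single letters as
      # strings and only resolve the usual true/false words
      yaml::read_yaml(path, handlers = list(
        "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE,
        "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE))
    }
  }, error = function(e) stop("config parse error: ", conditionMessage(e)))
  if (is.null(raw) || !is.list(raw) || !length(raw))
    stop("config parse error: empty or non-mapping config")
  schemas <- .engine_schemas()
  problems <- character(0)
  engine <- raw$engine
  if (is.null(engine) || !is.character(engine) ||
      !engine %in% names(schemas)) {
    problems <- c(problems, paste0(
      "engine must be one of: ", paste(names(schemas), collapse = ", ")))
    engine <- NA_character_
  }
  seed <- raw$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1 || seed != floor(seed))
    problems <- c(problems, "seed must be a single integer")
  params <- raw$parameters %||% list()
  if (!is.list(params))
    problems <- c(problems, "parameters must be a mapping")
  top_unknown <- setdiff(names(raw), c("engine", "seed", "out", "parameters"))
  if (length(top_unknown))
    problems <- c(problems, paste0(
      "unknown top-level keys: ", paste(top_unknown, collapse = ", "),
      " (valid: engine, seed, out, parameters)"))
  if (!is.na(engine) && is.list(params)) {
    sch <- schemas[[engine]]
    unknown <- setdiff(names(params), names(sch$keys))
    if (length(unknown))
      problems <- c(problems, paste0(
        "unknown keys for engine '", engine, "': ",
        paste(unknown, collapse = ", "), " (valid: ",
        paste(names(sch$keys), collapse = ", "), ")"))
    missing <- setdiff(sch$required, names(params))
    if (length(missing))
      problems <- c(problems, paste0(
        "missing required keys: ", paste(missing, collapse = ", ")))
    for (k in intersect(names(params), names(sch$keys))) {
      rule <- sch$keys[[k]]
      if (!rule$check(params[[k]]))
        problems <- c(problems, paste0(
          "key '", k, "': ", rule$msg, " (got ",
          paste(utils::head(format(params[[k]]), 3), collapse = ", "), ")"))
    }
  }
  if (length(problems))
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  structure(list(engine = engine, parameters = params,
                 seed = as.integer(seed), out = raw$out),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a result table or list
#'
#' JSON output carries the full structure plus the resolved config echo;
#' CSV output writes tables with a deterministic column order and the config
#' echo in a `<path>.config.json` sidecar.  Floats are written with 12
#' significant digits.
#'
#' @param result a data.frame or a list of scalars/vectors.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @param config optional [load_config()] result (or any list) echoed into
#'   the output.
#' @export
write_results <- function(result, path, format = c("json", "csv"),
                          config = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(result = result)
    if (!is.null(config)) payload$config <- unclass(config)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12,
                         pretty = TRUE, na = "null")
  } else {
    if (!is.data.frame(result))
      result <- as.data.frame(result, stringsAsFactors = FALSE)
    result <- result[, sort(names(result)), drop = FALSE]
    num <- vapply(result, is.numeric, logical(1))
    result[num] <- lapply(result[num], function(col) signif(col, 12))
    utils::write.csv(result, path, row.names = FALSE, quote = FALSE)
    if (!is.null(config))
      jsonlite::write_json(unclass(config), paste0(path, ".config.json"),
                           auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Render the escape-time surface
#'
#' Two-panel perspective plot of mean escape time over the `(E, N)` grid,
#' from two viewing angles.  Purely presentational; no numbers are asserted.
#'
#' @param surface data.frame from [escape_time_surface()] (or a CSV path to
#'   one) with columns `E`, `N`, `mean_tau`.
#' @param out_png output PNG path.
#' @param width,height device size in pixels.
#' @export
render_surface <- function(surface, out_png, width = 1200, height = 600) {
  if (is.character(surface)) surface <- utils::read.csv(surface)
  need <- c("E", "N", "mean_tau")
  if (!all(need %in% names(surface)))
    stop("surface table must contain columns: ", paste(need, collapse = ", "))
  if (!nrow(surface)) stop("empty surface table")
  Es <- sort(unique(surface$E)); Ns <- sort(unique(surface$N))
  if (length(Es) < 2 || length(Ns) < 2)
    warning("degenerate surface (single row or column); plot will be flat")
  z <- matrix(NA_real_, length(Es), length(Ns))
  for (i in seq_len(nrow(surface)))
    z[match(surface$E[i], Es), match(surface$N[i], Ns)] <-
      surface$mean_tau[i]
  grDevices::png(out_png, width = width, height = height)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (angle in c(35, 135)) {
    if (length(Es) < 2 || length(Ns) < 2) {
      graphics::plot(surface$N, surface$mean_tau, type = "b",
                     xlab = "N", ylab = "mean tau")
    } else {
      graphics::persp(Es, Ns, z, theta = angle, phi = 25,
                      xlab = "E (V/m)", ylab = "N (monomers)",
                      zlab = "mean tau (reduced time)",
                      ticktype = "detailed", col = "lightsteelblue",
                      main = sprintf("escape time, view %d", angle))
    }
  }
  invisible(out_png)
}
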