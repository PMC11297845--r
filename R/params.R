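#' Dimensional model parameters
#'
#' Construct and validate the dimensional parameter set for the 1-D
#' spindle-pole model: a spindle pole dragged through cytoplasm, centred by a
#' microtubule restoring force, and pulled toward two opposing cortices by
#' populations of force generators (dynein motors on elastic linkers).
#' Defaults are literature estimates for the system.
#'
#' @param xi_bar drag coefficient of the spindle pole (N s/m).
#' @param k_MT microtubule restoring-force stiffness (N/m).
#' @param k_g elastic-linker stiffness of a force generator (N/m).
#' @param f0 stall force of a motor head (N).
#' @param v0 unloaded walking speed of a motor head (m/s).
#' @param xi_g_bar drag coefficient of an unbound linker (N s/m).
#' @param gamma_bar tension sensitivity of unbinding (1/m); the unbinding
#'   rate is `omega_0_bar * exp(gamma_bar * y)` for linker extension `y`.
#' @param D_b_bar,D_u_bar diffusion coefficients of bound and unbound
#'   linker tips (m^2/s).
#' @param y_max_bar maximum linker extension (m).
#' @param omega_on_bar binding rate (1/s).
#' @param omega_0_bar unbinding rate coefficient at zero extension (1/s).
#' @param N number of force generators per cortex (non-negative integer).
#'
#' @return An object of class `spindle_dim_params` (a named list) with the
#'   derived stall length `y0 = f0/k_g` (m) and stall time `y0/v0` (s)
#'   attached as read-only fields.
#' @seealso [nondimensionalize()], [baseline_params()]
#' @export
#' @examples
#' d <- dim_params()
#' d$y0            # stall length, m
#' nondimensionalize(d)
dim_params <- function(xi_bar = 1e-6, k_MT = 4e-6, k_g = 8e-5,
                       f0 = 3e-12, v0 = 1.8e-6, xi_g_bar = 8e-8,
                       gamma_bar = 5.6e7, D_b_bar = 5e-15, D_u_bar = 5e-14,
                       y_max_bar = 2.16e-7, omega_on_bar = 0.15,
                       omega_0_bar = 0.05, N = 15L) {
  p <- list(xi_bar = xi_bar, k_MT = k_MT, k_g = k_g, f0 = f0, v0 = v0,
            xi_g_bar = xi_g_bar, gamma_bar = gamma_bar, D_b_bar = D_b_bar,
            D_u_bar = D_u_bar, y_max_bar = y_max_bar,
            omega_on_bar = omega_on_bar, omega_0_bar = omega_0_bar)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                            is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("dimensional parameters must be positive finite scalars: ",
         paste(bad, collapse = ", "))
  if (length(N) != 1L || is.na(N) || N < 0 || N != round(N))
    stop("N must be a non-negative integer")
  p$N <- as.integer(N)
  p$y0 <- f0 / k_g
  p$stall_time <- p$y0 / v0
  structure(p, class = "spindle_dim_params")
}

#' Nondimensionalise a dimensional parameter set
#'
#' Scales lengths on the stall length `y0 = f0/k_g` and times on the stall
#' time `y0/v0`. The component formulas are
#' `xi = xi_bar*v0/f0`, `K = k_MT/k_g`, `omega_on = omega_on_bar*y0/v0`,
#' `omega_0 = omega_0_bar*y0/v0`, `y_max = y_max_bar/y0`,
#' `gamma = gamma_bar*y0`, `D_b = D_b_bar/(y0*v0)`,
#' `Gamma = f0/(xi_g_bar*v0)`. The unbound diffusivity enters the model
#' only through the product `Gamma*D_u`, so the dimensional `D_u_bar`
#' maps to `D_u = D_u_bar/(y0*v0*Gamma)`.
#'
#' @param dim a [dim_params()] object.
#' @return A `spindle_params` object (see [baseline_params()]).
#' @export
nondimensionalize <- function(dim) {
  stopifnot(inherits(dim, "spindle_dim_params"))
  y0 <- dim$y0
  Gamma <- dim$f0 / (dim$xi_g_bar * dim$v0)
  spindle_params(
    xi = dim$xi_bar * dim$v0 / dim$f0,
    K = dim$k_MT / dim$k_g,
    omega_on = dim$omega_on_bar * y0 / dim$v0,
    omega_0 = dim$omega_0_bar * y0 / dim$v0,
    y_max = dim$y_max_bar / y0,
    gamma = dim$gamma_bar * y0,
    D_b = dim$D_b_bar / (y0 * dim$v0),
    D_u = dim$D_u_bar / (y0 * dim$v0 * Gamma),
    Gamma = Gamma,
    N = dim$N,
    y0 = y0, stall_time = dim$stall_time)
}

#' Nondimensional model parameters
#'
#' Container for the nondimensional parameter set of the spindle-pole model.
#' `baseline_params()` returns the baseline values used throughout:
#' `xi = 0.625`, `K = 0.05`, `omega_on = 0.003`, `omega_0 = 0.001`,
#' `y_max = 6`, `gamma = 2`, `D_b = 0.08`, `D_u = 0.04`, `Gamma = 20`.
#' These printed baselines take precedence over values recomputed from the
#' dimensional estimates (which round slightly differently).
#'
#' @param xi nondimensional spindle drag.
#' @param K nondimensional restoring stiffness (`k_MT/k_g`).
#' @param omega_on,omega_0 nondimensional binding / unbinding rates.
#' @param y_max maximum linker extension in stall lengths (must exceed 1 so
#'   the stall extension is interior).
#' @param gamma tension sensitivity of unbinding; `gamma > 1` (slip bond)
#'   is necessary for self-sustained oscillations.
#' @param D_b,D_u diffusivities of bound / unbound linker tips.
#' @param Gamma retraction rate of unbound linkers relative to the stall
#'   rate; the unbound advective velocity is `-Gamma*y` and the unbound
#'   diffusive flux carries `Gamma*D_u`.
#' @param N force generators per cortex; may be `NA` in a parameter set and
#'   supplied later to the operations that need it.
#' @param y0,stall_time optional dimensional scales (m, s) carried along for
#'   redimensionalisation of outputs.
#' @param ... in `baseline_params()`, fields overriding the baseline.
#' @return An object of class `spindle_params`.
#' @export
#' @examples
#' p <- baseline_params(N = 15)
#' p$gamma
#' baseline_params(D_b = 8e-3, D_u = 4e-3, N = 25)  # low-diffusivity variant
spindle_params <- function(xi, K, omega_on, omega_0, y_max, gamma,
                           D_b, D_u, Gamma, N = NA_integer_,
                           y0 = NA_real_, stall_time = NA_real_) {
  p <- list(xi = xi, K = K, omega_on = omega_on, omega_0 = omega_0,
            y_max = y_max, gamma = gamma, D_b = D_b, D_u = D_u,
            Gamma = Gamma)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                            is.finite(x) && x > 0, logical(1))]
  # gamma = 0 (no tension sensitivity) and omega_0 = 0 (no unbinding) are
  # legitimate limiting variants
  zero_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == 0
  bad <- setdiff(bad, c(if (zero_ok(gamma)) "gamma",
                        if (zero_ok(omega_0)) "omega_0"))
  if (length(bad))
    stop("nondimensional parameters must be positive finite scalars: ",
         paste(bad, collapse = ", "))
  if (y_max <= 1)
    stop("y_max must exceed 1 (the stall extension must be interior)")
  if (!is.na(N)) {
    if (N < 0 || N != round(N)) stop("N must be a non-negative integer")
    N <- as.integer(N)
  }
  p$N <- N
  p$y0 <- y0
  p$stall_time <- stall_time
  structure(p, class = "spindle_params")
}

#' @rdname spindle_params
#' @export
baseline_params <- function(..., N = NA_integer_) {
  args <- list(xi = 0.625, K = 0.05, omega_on = 0.003, omega_0 = 0.001,
               y_max = 6, gamma = 2, D_b = 0.08, D_u = 0.04, Gamma = 20,
               N = N)
  over <- list(...)
  unknown <- setdiff(names(over), names(args))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  args[names(over)] <- over
  do.call(spindle_params, args)
}

#' Derived parameters of the reduced ODE model
#'
#' Computes the parameter combinations that govern the reduced three-variable
#' ODE system: the binding affinity `rho = omega_0/omega_on`, the per-capita
#' drag `xi_hat = xi/N`, the per-capita restoring stiffness
#' `K_hat = K/(N*omega_on)`, and `lam = 1 + rho*exp(gamma)`, the factor by
#' which bound-population relaxation exceeds binding at the stall extension.
#'
#' @param p a `spindle_params` object.
#' @param N force generators per cortex; defaults to `p$N`.
#' @return An object of class `spindle_derived`: a list with `rho`,
#'   `xi_hat`, `K_hat`, `lam`, plus `gamma`, `omega_on`, `omega_0`, `N`
#'   carried over for downstream analyses.
#' @export
#' @examples
#' derive_params(baseline_params(), N = 15)$K_hat  # 0.05/(15*0.003)
derive_params <- function(p, N = p$N) {
  stopifnot(inherits(p, "spindle_params"))
  if (is.na(N) || N <= 0)
    stop("N must be a positive integer (hatted parameters are per capita)")
  rho <- p$omega_0 / p$omega_on
  structure(list(rho = rho,
                 xi_hat = p$xi / N,
                 K_hat = p$K / (N * p$omega_on),
                 lam = 1 + rho * exp(p$gamma),
                 gamma = p$gamma,
                 omega_on = p$omega_on,
                 omega_0 = p$omega_0,
                 N = N),
            class = "spindle_derived")
}

#' @export
print.spindle_dim_params <- function(x, ...) {
  cat("Dimensional spindle-pole model parameters\n")
  flds <- setdiff(names(x), c("N", "y0", "stall_time"))
  for (f in flds) cat(sprintf("  %-12s %g\n", f, x[[f]]))
  cat(sprintf("  %-12s %d\n", "N", x$N))
  cat(sprintf("  derived: y0 = %g m, stall time = %g s\n", x$y0, x$stall_time))
  invisible(x)
}

#' @export
print.spindle_params <- function(x, ...) {
  cat("Nondimensional spindle-pole model parameters\n")
  for (f in c("xi", "K", "omega_on", "omega_0", "y_max", "gamma",
              "D_b", "D_u", "Gamma"))
    cat(sprintf("  %-9s %g\n", f, x[[f]]))
  cat(sprintf("  N        %s\n", ifelse(is.na(x$N), "<unset>", x$N)))
  invisible(x)
}

#' @export
print.spindle_derived <- function(x, ...) {
  cat(sprintf(
    "Reduced-model parameters (N = %d): rho = %g, xi_hat = %g, K_hat = %g, lam = %g\n",
    x$N, x$rho, x$xi_hat, x$K_hat, x$lam))
  invisible(x)
}

# ---- flat key=value config files ------------------------------------------

#' Read or write a flat key=value parameter file
#'
#' The config format is one `key=value` pair per line plus a `type` line that
#' is either `dimensional` (SI units, fields of [dim_params()]) or
#' `nondimensional` (unitless, fields of [spindle_params()]); the two forms
#' are mutually exclusive. Blank lines and lines starting with `#` are
#' ignored. A dimensional file is nondimensionalised on read.
#'
#' @param path file path.
#' @param N optional override for the number of force generators per cortex.
#' @return `read_params_config()` returns a `spindle_params` object.
#' @export
read_params_config <- function(path, N = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed config line(s) in ", path)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  type <- vals[keys == "type"]
  if (length(type) != 1L || !type %in% c("dimensional", "nondimensional"))
    stop("config must contain exactly one line 'type=dimensional' or ",
         "'type=nondimensional'")
  keep <- keys != "type"
  args <- as.list(as.numeric(vals[keep]))
  names(args) <- keys[keep]
  if (!is.null(N)) args$N <- N
  if (type == "dimensional") {
    nondimensionalize(do.call(dim_params, args))
  } else {
    known <- names(formals(spindle_params))
    unknown <- setdiff(names(args), known)
    if (length(unknown))
      stop("unknown nondimensional key(s): ", paste(unknown, collapse = ", "))
    defaults <- baseline_params()
    full <- defaults[c("xi", "K", "omega_on", "omega_0", "y_max", "gamma",
                       "D_b", "D_u", "Gamma", "N")]
    full[names(args)] <- args
    do.call(spindle_params, full)
  }
}

#' @rdname read_params_config
#' @param p a `spindle_params` or `spindle_dim_params` object to serialise.
#' @export
write_params_config <- function(p, path) {
  if (inherits(p, "spindle_dim_params")) {
    flds <- setdiff(names(p), c("y0", "stall_time"))
    type <- "dimensional"
  } else if (inherits(p, "spindle_params")) {
    flds <- c("xi", "K", "omega_on", "omega_0", "y_max", "gamma",
              "D_b", "D_u", "Gamma", if (!is.na(p$N)) "N")
    type <- "nondimensional"
  } else stop("p must be a parameter object")
  out <- c(paste0("type=", type),
           vapply(flds, function(f)
             sprintf("%s=%.15g", f, as.numeric(p[[f]])), ""))
  writeLines(out, path)
  invisible(path)
}
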