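#' Right-hand side of the reduced three-variable ODE model
#'
#' The asymptotic reduction of the mean-field model in the slow-binding limit
#' (`omega_on ~ omega_0 ~ sqrt(D_b) ~ sqrt(D_u) << 1`), in rescaled variables
#' `z_tilde = omega_on * z`, `t_tilde = omega_on * t`:
#' \deqn{(\hat\xi + \hat B^+ + \hat B^-)\,\tilde z_{\tilde t} + \hat K \tilde z
#'   = \hat B^+ - \hat B^-}
#' \deqn{\hat B^\pm_{\tilde t} = 1 - (1 + \rho e^{\gamma(1 \mp
#'   \tilde z_{\tilde t})})\,\hat B^\pm}
#' `B_hat` approximates (a scaled version of) the bound-density peak height.
#' The first equation is solved explicitly for the velocity, making the
#' system an explicit ODE.
#'
#' @param state numeric `c(z_tilde, B_hat_plus, B_hat_minus)`.
#' @param d a `spindle_derived` object from [derive_params()].
#' @return Named list with `dz_tilde`, `dB_plus`, `dB_minus` and the
#'   velocity `z_tilde_dot` itself.
#' @export
#' @examples
#' d <- derive_params(baseline_params(), N = 15)
#' reduced_rhs(c(0, 1 / d$lam, 1 / d$lam), d)  # equilibrium: all zero
reduced_rhs <- function(state, d) {
  zt <- state[1]; Bp <- state[2]; Bm <- state[3]
  w <- (Bp - Bm - d$K_hat * zt) / (d$xi_hat + Bp + Bm)
  list(dz_tilde = w,
       dB_plus = 1 - (1 + d$rho * exp(d$gamma * (1 - w))) * Bp,
       dB_minus = 1 - (1 + d$rho * exp(d$gamma * (1 + w))) * Bm,
       z_tilde_dot = w)
}

# typical detachment extension of the Grill variant: root in [0, y_max] of
# (omega_0 e^{gamma y} + 1) y - 1 = -+ w   (monotone increasing in y)
grill_extension <- function(w_signed, omega_0, gamma, y_max, tol = 1e-12) {
  f <- function(y) (omega_0 * exp(gamma * y) + 1) * y - 1 - w_signed
  if (f(0) > 0 || f(y_max) < 0)
    stop("no typical-extension root in [0, y_max]")
  stats::uniroot(f, c(0, y_max), tol = tol)$root
}

#' Right-hand side of the Grill-variant ODE model
#'
#' The heuristic ODE system with an implicitly defined typical detachment
#' extension `y_tilde`:
#' \deqn{\hat\xi \tilde z_{\tilde t} + \hat K \tilde z =
#'   \hat B^+ \tilde y^+ - \hat B^- \tilde y^-}
#' \deqn{\hat B^\pm_{\tilde t} = 1 - (1 + \rho e^{\gamma \tilde y^\pm})
#'   \hat B^\pm, \qquad
#'   \mp \tilde z_{\tilde t} = (\omega_0 e^{\gamma \tilde y^\pm} + 1)
#'   \tilde y^\pm - 1.}
#' The velocity equation and the two implicit extension equations are solved
#' jointly at each evaluation: the residual of the velocity equation is
#' strictly monotone in the velocity, so a bracketed scalar root-solve (with
#' nested bracketed solves for `y_tilde`) gives the consistent pair. As
#' `omega_0 -> 0`, `y_tilde -> 1 -/+ z_tilde_dot` and the system reduces to
#' [reduced_rhs()].
#'
#' @inheritParams reduced_rhs
#' @param y_max maximum linker extension (bracket for the implicit solve).
#' @return Named list with derivatives, the velocity, and `y_tilde_plus`,
#'   `y_tilde_minus`.
#' @export
grill_rhs <- function(state, d, y_max = 6) {
  zt <- state[1]; Bp <- state[2]; Bm <- state[3]
  resid <- function(w) {
    yp <- grill_extension(-w, d$omega_0, d$gamma, y_max)
    ym <- grill_extension(w, d$omega_0, d$gamma, y_max)
    d$xi_hat * w + d$K_hat * zt - Bp * yp + Bm * ym
  }
  # residual is monotone increasing in w; w is confined to (-1-e, 1+e)
  lo <- -1 + 1e-10; hi <- 1 - 1e-10
  # expand if the root saturates the physical bracket
  if (resid(lo) > 0 || resid(hi) < 0)
    stop("no consistent spindle velocity: typical extension leaves [0, y_max]")
  w <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  yp <- grill_extension(-w, d$omega_0, d$gamma, y_max)
  ym <- grill_extension(w, d$omega_0, d$gamma, y_max)
  list(dz_tilde = w,
       dB_plus = 1 - (1 + d$rho * exp(d$gamma * yp)) * Bp,
       dB_minus = 1 - (1 + d$rho * exp(d$gamma * ym)) * Bm,
       z_tilde_dot = w, y_tilde_plus = yp, y_tilde_minus = ym)
}

ode_trajectory <- function(out, d, kind) {
  zt <- out[, 2]; Bp <- out[, 3]; Bm <- out[, 4]
  w <- (Bp - Bm - d$K_hat * zt) / (d$xi_hat + Bp + Bm)
  traj <- data.frame(t = out[, 1] / d$omega_on,
                     z = zt / d$omega_on,
                     t_tilde = out[, 1], z_tilde = zt,
                     B_hat_plus = Bp, B_hat_minus = Bm,
                     z_tilde_dot = w,
                     y_c_plus = 1 - w, y_c_minus = 1 + w)
  attr(traj, "derived") <- d
  attr(traj, "kind") <- kind
  class(traj) <- c("spindle_trajectory", "data.frame")
  traj
}

#' Integrate the reduced or Grill-variant ODE model
#'
#' Adaptive integration (lsoda) of [reduced_rhs()] or [grill_rhs()].
#' Time and position are reported both in rescaled ODE units
#' (`t_tilde`, `z_tilde`) and in model units (`t = t_tilde/omega_on`,
#' `z = z_tilde/omega_on`), together with the bound-peak locations
#' `y_c+- = 1 -/+ z_tilde_dot` used for limit-cycle loops.
#'
#' @param d a `spindle_derived` object.
#' @param ics initial `c(z_tilde, B_plus, B_minus)`; the default displaces
#'   the spindle slightly and detunes the bound amplitudes from the fixed
#'   point `1/lam` to break symmetry.
#' @param t_end_tilde horizon in rescaled time.
#' @param sample_every_tilde output interval in rescaled time.
#' @param y_max bracket for the Grill implicit solve.
#' @param rtol,atol integrator tolerances.
#' @return A `spindle_trajectory` data frame (see Details).
#' @export
#' @examples
#' d <- derive_params(baseline_params(), N = 25)
#' traj <- integrate_reduced(d, t_end_tilde = 60)
integrate_reduced <- function(d, ics = c(0.1, 1 / d$lam + 1e-3,
                                         1 / d$lam - 1e-3),
                              t_end_tilde = 100, sample_every_tilde = 0.01,
                              rtol = 1e-10, atol = 1e-12) {
  f <- function(t, y, parms) {
    r <- reduced_rhs(y, d)
    list(c(r$dz_tilde, r$dB_plus, r$dB_minus))
  }
  out <- deSolve::ode(ics, seq(0, t_end_tilde, by = sample_every_tilde), f,
                      NULL, method = "lsoda", rtol = rtol, atol = atol)
  ode_trajectory(out, d, "reduced_ode")
}

#' @rdname integrate_reduced
#' @export
integrate_grill <- function(d, ics = c(0.1, 1 / d$lam + 1e-3,
                                       1 / d$lam - 1e-3),
                            t_end_tilde = 100, sample_every_tilde = 0.01,
                            y_max = 6, rtol = 1e-8, atol = 1e-10) {
  f <- function(t, y, parms) {
    r <- grill_rhs(y, d, y_max)
    list(c(r$dz_tilde, r$dB_plus, r$dB_minus))
  }
  out <- deSolve::ode(ics, seq(0, t_end_tilde, by = sample_every_tilde), f,
                      NULL, method = "lsoda", rtol = rtol, atol = atol)
  ode_trajectory(out, d, "grill_ode")
}

#' Displacement-velocity function of the slow relaxation phases
#'
#' In the strong-pulling limit (`K_hat -> 0`) the slow phases of the limit
#' cycle collapse onto the algebraic displacement-velocity relation
#' \deqn{G(w) = \hat B_0^+(w) - \hat B_0^-(w) -
#'   (\hat\xi + \hat B_0^+(w) + \hat B_0^-(w))\,w, \qquad
#'   \hat B_0^\pm(w) = \frac{1}{1 + \rho e^{\gamma(1 \mp w)}}.}
#' `G` is odd; for `gamma > 1` it has two interior turning points whose
#' `G`-values bound the relaxation cycle.
#'
#' @param w velocity-like argument (`z_tilde_dot`), vectorised.
#' @param d a `spindle_derived` object.
#' @export
G_function <- function(w, d) {
  Bp <- 1 / (1 + d$rho * exp(d$gamma * (1 - w)))
  Bm <- 1 / (1 + d$rho * exp(d$gamma * (1 + w)))
  Bp - Bm - (d$xi_hat + Bp + Bm) * w
}

#' Relaxation-oscillation amplitude estimate
#'
#' Locates the turning points of [G_function()] by bracketed root-solving on
#' `dG/dw` (sign changes found on a dense scan of `[-w_scan, w_scan]`),
#' evaluates `G` there, and estimates the peak-to-peak amplitude of the
#' relaxation cycle as `(G_max - G_min)/K_hat` (in `z_tilde` units; divide
#' by a further `omega_on` for `z` units). With `gamma <= 1` (or whenever
#' `dG/dw` has no sign change) there is no relaxation cycle.
#'
#' @param d a `spindle_derived` object.
#' @param w_scan half-width of the scanned velocity interval.
#' @return A list of class `relaxation_cycle`: `cycle` (logical),
#'   `w_minus`, `w_plus`, `G_max`, `G_min`, `amplitude`.
#' @export
#' @examples
#' relaxation_amplitude(derive_params(baseline_params(), N = 15))
relaxation_amplitude <- function(d, w_scan = 3) {
  dG <- function(w) {
    e <- 1e-7
    (G_function(w + e, d) - G_function(w - e, d)) / (2 * e)
  }
  ws <- seq(-w_scan, w_scan, length.out = 4001)
  dv <- dG(ws)
  sc <- which(diff(sign(dv)) != 0)
  if (d$gamma <= 1 || length(sc) < 2)
    return(structure(list(cycle = FALSE, w_minus = NA_real_,
                          w_plus = NA_real_, G_max = NA_real_,
                          G_min = NA_real_, amplitude = NA_real_),
                     class = "relaxation_cycle"))
  roots <- vapply(sc, function(i)
    stats::uniroot(dG, c(ws[i], ws[i + 1]), tol = 1e-12)$root, 0)
  w_minus <- min(roots); w_plus <- max(roots)
  Gv <- G_function(c(w_minus, w_plus), d)
  structure(list(cycle = TRUE, w_minus = w_minus, w_plus = w_plus,
                 G_max = max(Gv), G_min = min(Gv),
                 amplitude = (max(Gv) - min(Gv)) / d$K_hat),
            class = "relaxation_cycle")
}

#' @export
print.relaxation_cycle <- function(x, ...) {
  if (!x$cycle) {
    cat("No relaxation cycle (G is monotone)\n")
  } else {
    cat(sprintf(
      "Relaxation cycle: turning points w = %.5f, %.5f; G in [%.5f, %.5f];\n",
      x$w_minus, x$w_plus, x$G_min, x$G_max))
    cat(sprintf("  peak-to-peak amplitude (G_max - G_min)/K_hat = %.4f\n",
                x$amplitude))
  }
  invisible(x)
}
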