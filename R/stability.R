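#' Linear stability of the reduced ODE model
#'
#' Linearising the reduced system about its fixed point
#' (`B_hat+- = 1/lam`, `z_tilde = 0`) gives the characteristic equation
#' \deqn{(s + \lambda)\left(s^2 + s\Big(\lambda +
#'   \frac{\hat K\lambda}{\lambda\hat\xi + 2} -
#'   \frac{2\gamma(\lambda - 1)}{\lambda\hat\xi + 2}\Big) +
#'   \frac{\hat K\lambda^2}{\lambda\hat\xi + 2}\right) = 0,}
#' whose quadratic factor carries the growth rate `mu` and angular frequency
#' `Omega` of the oscillatory pair. A parameter point is classed oscillatory
#' when `mu > 0` and `Omega^2 > 0` (boundary ties resolve to
#' non-oscillatory).
#'
#' @param d a `spindle_derived` object from [derive_params()].
#' @return A list of class `stability_result`: `roots` (three complex
#'   characteristic roots, the real root `-lam` last), `mu`, `Omega`
#'   (`NA` when the pair is real), `period_t_tilde`, `period_t`
#'   (`2*pi/(Omega*omega_on)`), and `oscillatory`.
#' @export
#' @examples
#' characteristic_roots(derive_params(baseline_params(), N = 15))
characteristic_roots <- function(d) {
  den <- d$lam * d$xi_hat + 2
  b <- d$lam + d$K_hat * d$lam / den - 2 * d$gamma * (d$lam - 1) / den
  cc <- d$K_hat * d$lam^2 / den
  disc <- b^2 - 4 * cc
  if (disc < 0) {
    pair <- complex(real = -b / 2, imaginary = c(1, -1) * sqrt(-disc) / 2)
  } else {
    pair <- complex(real = (-b + c(1, -1) * sqrt(disc)) / 2, imaginary = 0)
  }
  mu <- (2 * d$gamma * (d$lam - 1) - d$K_hat * d$lam - d$lam * den) / (2 * den)
  Omega2 <- cc - b^2 / 4
  Omega <- if (Omega2 > 0) sqrt(Omega2) else NA_real_
  osc <- isTRUE(Omega2 > 0 && mu > 0)
  structure(list(roots = c(pair, complex(real = -d$lam, imaginary = 0)),
                 mu = mu, Omega = Omega, Omega2 = Omega2,
                 period_t_tilde = if (!is.na(Omega)) 2 * pi / Omega else NA_real_,
                 period_t = if (!is.na(Omega)) 2 * pi / (Omega * d$omega_on)
                            else NA_real_,
                 oscillatory = osc, derived = d),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Linear stability of the reduced spindle model\n")
  cat("  roots:", paste(format(x$roots, digits = 6), collapse = ", "), "\n")
  cat(sprintf("  growth rate mu = %.6g, Omega = %s\n", x$mu,
              ifelse(is.na(x$Omega), "none (real pair)",
                     format(x$Omega, digits = 6))))
  if (!is.na(x$Omega))
    cat(sprintf("  period: %.6g t~ units, %.6g t units\n",
                x$period_t_tilde, x$period_t))
  cat("  oscillatory:", x$oscillatory, "\n")
  invisible(x)
}

#' Neutral-stability threshold of the per-capita stiffness
#'
#' On the neutral curve (`mu = 0`) the per-capita restoring stiffness
#' satisfies `K_hat = 2*(gamma*(lam - 1)/lam - 1) - xi_hat*lam`. A
#' non-positive value signals that no physical neutral point exists at
#' these parameters.
#'
#' @param d a `spindle_derived` object.
#' @export
neutral_K <- function(d) {
  2 * (d$gamma * (d$lam - 1) / d$lam - 1) - d$xi_hat * d$lam
}

#' Upper binding-rate threshold for oscillations
#'
#' In the weak-restoring limit the oscillatory wedge in `(N, omega_on)`
#' space closes at `omega_on_dagger = (gamma - 1)*omega_0*exp(gamma)`:
#' oscillations require slip-bond behaviour (`gamma > 1`) and
#' `omega_on < omega_on_dagger`. For `gamma <= 1` the window is empty and
#' the threshold is reported as 0.
#'
#' @param gamma tension sensitivity of unbinding.
#' @param omega_0 unbinding rate coefficient.
#' @export
#' @examples
#' omega_dagger(gamma = 2, omega_0 = 0.001)  # 0.0073891
omega_dagger <- function(gamma, omega_0) {
  if (gamma <= 1) return(0)
  (gamma - 1) * omega_0 * exp(gamma)
}

# growth rate as a function of N at fixed omega_on (for curve tracing)
mu_of_N <- function(N, p) characteristic_roots(derive_params(p, N))$mu

# The neutral condition K_hat = 2(gamma(lam-1)/lam - 1) - xi_hat*lam is
# linear in N once multiplied through, so mu(N) = 0 has at most one root at
# fixed omega_on:
#   N_c = (K/omega_on + xi*lam) / (2*(gamma*(lam-1)/lam - 1)).
# A coarse-scan bisection on mu(N) is kept as the numerical fallback / check.
neutral_N_closed <- function(p, omega_on = p$omega_on) {
  lam <- 1 + (p$omega_0 / omega_on) * exp(p$gamma)
  den <- 2 * (p$gamma * (lam - 1) / lam - 1)
  if (den <= 0) return(NA_real_)   # omega_on >= omega_dagger: no threshold
  (p$K / omega_on + p$xi * lam) / den
}

neutral_N_roots <- function(p, N_range = c(0.5, 1e4), n_scan = 400) {
  Ns <- exp(seq(log(N_range[1]), log(N_range[2]), length.out = n_scan))
  mus <- vapply(Ns, mu_of_N, 0, p = p)
  sc <- which(diff(sign(mus)) != 0)
  vapply(sc, function(i)
    stats::uniroot(mu_of_N, c(Ns[i], Ns[i + 1]), p = p, tol = 1e-10)$root, 0)
}

#' Neutral stability curve in the (N, omega_on) plane
#'
#' The oscillatory region is a wedge: at fixed `omega_on` below the
#' asymptote `omega_on_dagger` the neutral condition has exactly one root
#' `N_c(omega_on)` (it is linear in `N`), and disturbances grow for all
#' `N > N_c`. Viewed at fixed `N`, the boundary is crossed twice — the
#' wedge's lower branch, where `N_c` falls with `omega_on`, and its upper
#' branch, where `N_c` rises and diverges as `omega_on -> omega_on_dagger`.
#' For each grid value this function reports `N_c` in `N_lower` or
#' `N_upper` according to the branch (split at the nose of the wedge),
#' together with the neutral frequency and period, the large-N lower-branch
#' approximation `N ~ (K + xi*omega_0*exp(gamma))/(2*omega_on*(gamma - 1))`,
#' the weak-restoring (`K_hat -> 0`) curve
#' `N = xi*(omega_on + omega_0*e^gamma)^2 /
#'  (2*omega_on*(omega_0*e^gamma*(gamma - 1) - omega_on))`,
#' and the Grill-variant threshold from [grill_comparators()].
#'
#' @param p a `spindle_params` object (its `N` is ignored).
#' @param omega_on grid of binding rates.
#' @return A list of class `neutral_curve`: a data frame `curve` with
#'   columns `omega_on`, `N_c`, `N_lower`, `N_upper`, `K_hat`, `Omega`,
#'   `period_t`, `N_lowK`, `N_largeN`, `grill_N_c`, plus `omega_dagger`,
#'   `omega_nose` (binding rate at the wedge's nose) and
#'   `N_min = xi/(gamma - 1)`, the smallest generator number that can
#'   sustain oscillations in the weak-restoring limit.
#' @export
neutral_curve <- function(p, omega_on = seq(5e-4, 7e-3, length.out = 40)) {
  stopifnot(inherits(p, "spindle_params"))
  if (p$gamma <= 1) {
    return(structure(list(curve = data.frame(), omega_dagger = 0,
                          omega_nose = NA_real_, N_min = Inf),
                     class = "neutral_curve"))
  }
  wd <- omega_dagger(p$gamma, p$omega_0)
  w_nose <- stats::optimize(function(w) neutral_N_closed(p, w),
                            c(wd * 1e-3, wd * (1 - 1e-9)))$minimum
  rows <- lapply(omega_on, function(w) {
    pw <- p; pw$omega_on <- w
    Nc <- neutral_N_closed(pw)
    groots <- grill_neutral_N_roots(pw)
    if (!is.na(Nc)) {
      dl <- derive_params(pw, Nc)
      Om <- sqrt(dl$K_hat * dl$lam^2 / (2 + dl$xi_hat * dl$lam))
      Kh <- dl$K_hat
    } else {
      Om <- NA_real_; Kh <- NA_real_
    }
    denom <- p$omega_0 * exp(p$gamma) * (p$gamma - 1) - w
    data.frame(omega_on = w, N_c = Nc,
               N_lower = if (!is.na(Nc) && w <= w_nose) Nc else NA_real_,
               N_upper = if (!is.na(Nc) && w > w_nose) Nc else NA_real_,
               K_hat = Kh, Omega = Om,
               period_t = if (!is.na(Om)) 2 * pi / (Om * w) else NA_real_,
               N_lowK = if (denom > 0)
                 p$xi * (w + p$omega_0 * exp(p$gamma))^2 / (2 * w * denom)
               else NA_real_,
               N_largeN = (p$K + p$xi * p$omega_0 * exp(p$gamma)) /
                 (2 * w * (p$gamma - 1)),
               grill_N_c = if (length(groots)) min(groots) else NA_real_)
  })
  structure(list(curve = do.call(rbind, rows), omega_dagger = wd,
                 omega_nose = w_nose, N_min = p$xi / (p$gamma - 1),
                 params = p),
            class = "neutral_curve")
}

#' Closed-form period predictions
#'
#' Evaluates the available closed forms for the oscillation period, each in
#' rescaled (`t_tilde`) and model (`t`) time, with its limit regime
#' labelled and flagged when evaluated outside its validity:
#' * `"neutral"`: `Omega^2 = K_hat*lam^2/(2 + xi_hat*lam)` at the supplied
#'   `(p, N)` — exact on the neutral curve, an approximation elsewhere.
#' * `"weak_restoring"`: `T ~ 2*pi*sqrt((gamma-1)*N*omega_dagger/(K*gamma))`
#'   (`K_hat -> 0` along the neutral curve; requires
#'   `omega_on < omega_dagger`).
#' * `"large_N"`: `T = 2*pi*(omega_on/omega_dagger) *
#'   sqrt((gamma-1)*(K + 2*xi*omega_0*e^gamma)/K)` (large `N`,
#'   `N*omega_on = O(1)`).
#'
#' @param p a `spindle_params` object.
#' @param N generators per cortex.
#' @return Data frame with columns `regime`, `period_t_tilde`, `period_t`,
#'   `valid`.
#' @export
period_predictions <- function(p, N = p$N) {
  d <- derive_params(p, N)
  wd <- omega_dagger(p$gamma, p$omega_0)
  Om2 <- d$K_hat * d$lam^2 / (2 + d$xi_hat * d$lam)
  T_neutral <- 2 * pi / sqrt(Om2)
  T_weakK <- if (wd > 0)
    2 * pi * sqrt((p$gamma - 1) * N * wd / (p$K * p$gamma)) else NA_real_
  T_largeN <- if (wd > 0)
    2 * pi * (p$omega_on / wd) *
      sqrt((p$gamma - 1) * (p$K + 2 * p$xi * p$omega_0 * exp(p$gamma)) / p$K)
  else NA_real_
  data.frame(
    regime = c("neutral", "weak_restoring", "large_N"),
    period_t_tilde = c(T_neutral, T_weakK, T_largeN),
    period_t = c(T_neutral, T_weakK, T_largeN) / p$omega_on,
    valid = c(Om2 > 0, wd > 0 && p$omega_on < wd, wd > 0))
}

#' Grill-variant stability comparators
#'
#' The neutral frequency and threshold of the Grill-variant ODEs, which keep
#' `omega_0`- and `omega_on`-dependent correction terms:
#' `Omega^2 = K_hat*lam^2*(1 + (gamma+1)*omega_0*e^gamma) /
#'  (xi_hat*lam*(1 + (gamma+1)*omega_0*e^gamma) + 2)` and
#' `K_hat = 2*(gamma*(lam-1)/lam - 1) /
#'  (omega_on*(lam-1)*(gamma+1) + 1) - xi_hat*lam`.
#' Both reduce to the reduced-model forms when `omega_0 ~ omega_on << 1`.
#'
#' @param d a `spindle_derived` object.
#' @return List with `Omega2` and `K_hat_threshold`.
#' @export
grill_comparators <- function(d) {
  q <- 1 + (d$gamma + 1) * d$omega_0 * exp(d$gamma)
  list(Omega2 = d$K_hat * d$lam^2 * q / (d$xi_hat * d$lam * q + 2),
       K_hat_threshold =
         2 * (d$gamma * (d$lam - 1) / d$lam - 1) /
           (d$omega_on * (d$lam - 1) * (d$gamma + 1) + 1) -
           d$xi_hat * d$lam)
}

# Grill-variant neutral residual in N at fixed omega_on
grill_neutral_N_roots <- function(p, N_range = c(0.5, 1e4), n_scan = 400) {
  res <- function(N) {
    d <- derive_params(p, N)
    d$K_hat - grill_comparators(d)$K_hat_threshold
  }
  Ns <- exp(seq(log(N_range[1]), log(N_range[2]), length.out = n_scan))
  rs <- vapply(Ns, res, 0)
  sc <- which(diff(sign(rs)) != 0)
  vapply(sc, function(i)
    stats::uniroot(res, c(Ns[i], Ns[i + 1]), tol = 1e-10)$root, 0)
}
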