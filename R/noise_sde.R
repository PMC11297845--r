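#' Stoichiometric formulation of the linearised kinetic model
#'
#' With the tension exponential linearised
#' (`exp(+-gamma*z_tilde_dot) ~ 1 +- gamma*z_tilde_dot`), the reduced ODE
#' system is a chemical kinetic scheme with eight reactions on the state
#' `x = (B_hat+, B_hat-, z_tilde)`. `stoich_matrix()` returns the 3x8
#' stoichiometric matrix and `propensities()` the state-dependent reaction
#' rates, with the auxiliary velocity factor
#' `a = gamma*(B+ - B- - K_hat*z)/(xi_hat + B+ + B-)`.
#'
#' @return `stoich_matrix()`: integer 3x8 matrix.
#' @export
stoich_matrix <- function() {
  matrix(c(1, -1, 0, 1, 0, 0, 0, 0,
           1, 0, -1, 0, -1, 0, 0, 0,
           0, 0, 0, 0, 0, 1, -1, -1),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("B_plus", "B_minus", "z_tilde"), NULL))
}

#' @rdname stoich_matrix
#' @param state numeric `c(B_plus, B_minus, z_tilde)`.
#' @param d a `spindle_derived` object.
#' @return `propensities()`: numeric vector of the eight reaction rates.
#' @export
propensities <- function(state, d) {
  Bp <- state[1]; Bm <- state[2]; z <- state[3]
  denom <- d$xi_hat + Bp + Bm
  a <- d$gamma * (Bp - Bm - d$K_hat * z) / denom
  re <- d$rho * exp(d$gamma)
  c(1, Bp * (1 + re), Bm * (1 + re), re * Bp * a, re * Bm * a,
    Bp / denom, Bm / denom, d$K_hat * z / denom)
}

#' Correlation (diffusion) matrix of the kinetic scheme
#'
#' `D = (1/2) * sum_i nu_i nu_i^T a_i` over the eight reactions; in closed
#' form
#' \deqn{D = \tfrac12 \begin{pmatrix}
#'  1 + \hat B^+(\lambda + \rho e^\gamma a) & 1 & 0\\
#'  1 & 1 + \hat B^-(\lambda + \rho e^\gamma a) & 0\\
#'  0 & 0 & (\hat B^+ + \hat B^- + \hat K\tilde z)/(\hat\xi + \hat B^+ +
#'  \hat B^-)\end{pmatrix}.}
#' At the equilibrium (`B+- = 1/lam`, `z = 0`) this reduces to
#' [correlation_matrix_star()].
#'
#' @inheritParams propensities
#' @export
correlation_matrix <- function(state, d) {
  Bp <- state[1]; Bm <- state[2]; z <- state[3]
  denom <- d$xi_hat + Bp + Bm
  a <- d$gamma * (Bp - Bm - d$K_hat * z) / denom
  re <- d$rho * exp(d$gamma)
  0.5 * matrix(c(1 + Bp * (d$lam + re * a), 1, 0,
                 1, 1 + Bm * (d$lam + re * a), 0,
                 0, 0, (Bp + Bm + d$K_hat * z) / denom),
               nrow = 3, byrow = TRUE)
}

#' @rdname correlation_matrix
#' @export
correlation_matrix_star <- function(d) {
  matrix(c(1, 0.5, 0,
           0.5, 1, 0,
           0, 0, 1 / (2 + d$xi_hat * d$lam)), nrow = 3, byrow = TRUE)
}

#' Jacobian of the linearised kinetic model at equilibrium
#'
#' \deqn{J^* = \frac{1}{2 + \lambda\hat\xi}\begin{pmatrix}
#'  (\lambda-1)\gamma - \lambda(2+\lambda\hat\xi) & -(\lambda-1)\gamma &
#'   -\hat K(\lambda-1)\gamma\\
#'  -(\lambda-1)\gamma & (\lambda-1)\gamma - \lambda(2+\lambda\hat\xi) &
#'   \hat K(\lambda-1)\gamma\\
#'  \lambda & -\lambda & -\hat K\lambda \end{pmatrix}}
#' Its eigenvalues coincide with the characteristic roots of the reduced
#' model's linear stability problem.
#'
#' @param d a `spindle_derived` object.
#' @export
#' @examples
#' eigen(jacobian_star(derive_params(baseline_params(), N = 15)))$values
jacobian_star <- function(d) {
  g <- (d$lam - 1) * d$gamma
  q <- 2 + d$lam * d$xi_hat
  (1 / q) * matrix(c(g - d$lam * q, -g, -d$K_hat * g,
                     -g, g - d$lam * q, d$K_hat * g,
                     d$lam, -d$lam, -d$K_hat * d$lam),
                   nrow = 3, byrow = TRUE)
}

#' First-order eigenvalue perturbation off the neutral curve
#'
#' Starting from a neutrally stable point (`K_hat_c`, `xi_hat_c` on the
#' neutral curve, frequency `Omega_c`), a fractional change in generator
#' number `epsilon = delta_N/N` maps to `K_hat = K_hat_c*(1 - epsilon)`,
#' `xi_hat = xi_hat_c*(1 - epsilon)` and shifts the critical pair to
#' \deqn{s = \frac{\epsilon\lambda(\hat K_c + \lambda\hat\xi_c)}
#'  {2(2 + \lambda\hat\xi_c)} \pm i\,\Omega_c\Big(1 -
#'  \frac{\epsilon}{2 + \lambda\hat\xi_c}\Big) + O(\epsilon^2),}
#' so increasing `N` (`epsilon > 0`) destabilises.
#'
#' @param d_c a `spindle_derived` object at the neutral point.
#' @param epsilon fractional change `delta_N/N`.
#' @return Complex pair (length-2 vector).
#' @export
perturbed_eigenvalues <- function(d_c, epsilon) {
  q <- 2 + d_c$lam * d_c$xi_hat
  Omega_c <- sqrt(d_c$K_hat * d_c$lam^2 / q)
  re <- epsilon * d_c$lam * (d_c$K_hat + d_c$lam * d_c$xi_hat) / (2 * q)
  im <- Omega_c * (1 - epsilon / q)
  complex(real = re, imaginary = c(im, -im))
}

#' Stationary covariance of the linear-noise model
#'
#' Solves the Lyapunov equation `J* sigma + sigma J*^T = -2 D*` for the
#' stationary covariance of `(B_hat+, B_hat-, z_tilde)` deviations (via the
#' Kronecker-vectorised linear system). Requires all eigenvalues of `J*` to
#' have negative real part. `sigma[3, 3]` is the stationary variance `f` of
#' the spindle position `z_tilde`, and `sqrt(f)/omega_on` estimates the
#' root-mean-square amplitude of noise-driven oscillations in `z` units.
#'
#' @param J_star,D_star Jacobian and correlation matrix at equilibrium
#'   (defaults computed from `d`).
#' @param d a `spindle_derived` object (used for defaults).
#' @return A list of class `covariance_solution`: `sigma`, `f`
#'   (`= sigma[3, 3]`), `sqrt_f`.
#' @export
#' @examples
#' solve_lyapunov(d = derive_params(baseline_params(), N = 15))$f
solve_lyapunov <- function(J_star = jacobian_star(d),
                           D_star = correlation_matrix_star(d), d = NULL) {
  ev <- eigen(J_star, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("stationary covariance undefined: equilibrium is not stable")
  n <- nrow(J_star)
  A <- kronecker(diag(n), J_star) + kronecker(J_star, diag(n))
  sigma <- matrix(solve(A, as.vector(-2 * D_star)), n, n)
  sigma <- (sigma + t(sigma)) / 2
  structure(list(sigma = sigma, f = sigma[n, n], sqrt_f = sqrt(sigma[n, n])),
            class = "covariance_solution")
}

#' Printed 6x6 coefficient system for the covariance entries
#'
#' The Lyapunov equation written out for the six distinct entries
#' `(a, b, c, d, e, f)` of the symmetric covariance, as a dense 6x6 linear
#' system in terms of `(lam, gamma, K_hat, xi_hat)` with
#' `alpha = (lam - 1)*gamma - lam*(2 + lam*xi_hat)`. Used as a cross-check
#' of [solve_lyapunov()].
#'
#' @param d a `spindle_derived` object.
#' @return Named numeric vector `c(a, b, c, d, e, f)`.
#' @export
covariance_coefficients <- function(d) {
  g <- (d$lam - 1) * d$gamma
  q <- 2 + d$lam * d$xi_hat
  al <- g - d$lam * q
  Kg <- d$K_hat * g
  L <- d$lam
  A <- matrix(c(
    al, -g, -Kg, 0, 0, 0,
    -g, 2 * al, Kg, -g, -Kg, 0,
    L, -L, al - d$K_hat * L, 0, -g, -Kg,
    0, -g, 0, al, Kg, 0,
    0, L, -g, -L, al - d$K_hat * L, Kg,
    0, 0, L, 0, -L, -d$K_hat * L), nrow = 6, byrow = TRUE)
  rhs <- c(-q, -q, 0, -q, 0, -1)
  stats::setNames(solve(A, rhs), c("a", "b", "c", "d", "e", "f"))
}

#' Closed-form stationary variance of the spindle position
#'
#' The `z_tilde` variance of the stationary linear-noise distribution in
#' closed form,
#' \deqn{f = \frac{4\gamma\alpha(\lambda-1) +
#'   \lambda^2(2+\lambda\hat\xi)(3+\lambda\hat\xi+\hat K)}
#'  {\hat K\lambda^2(2+\lambda\hat\xi)
#'   (\lambda(2+\lambda\hat\xi+\hat K-2\gamma)+2\gamma)},}
#' with `alpha = (lam-1)*gamma - lam*(2+lam*xi_hat)`. Agrees with the
#' numerical Lyapunov solution in the stable regime; a vanishing
#' denominator signals proximity to the neutral curve.
#'
#' @param d a `spindle_derived` object.
#' @export
f_closed_form <- function(d) {
  g <- d$gamma; L <- d$lam; xh <- d$xi_hat; Kh <- d$K_hat
  al <- (L - 1) * g - L * (2 + L * xh)
  den <- Kh * L^2 * (2 + L * xh) * (L * (2 + L * xh + Kh - 2 * g) + 2 * g)
  if (abs(den) < 1e-12)
    stop("denominator vanishes: parameters lie on or near the neutral curve")
  (4 * g * al * (L - 1) + L^2 * (2 + L * xh) * (3 + L * xh + Kh)) / den
}

#' Near-neutral approximation to the stationary variance
#'
#' Perturbing about the neutral curve with `epsilon = delta_N/N < 0`,
#' `f ~ (2*gamma*(lam-1)*K_hat_c + lam*(2 + lam*xi_hat_c)) /
#'  (2*K_hat_c*lam*(2 + lam*xi_hat_c)^2*(-Re(s)))`
#' where `s` is the perturbed eigenvalue. Diverges as the neutral curve is
#' approached and acts as an approximate upper bound on the exact variance.
#'
#' @param d_c derived parameters at the neutral point.
#' @param epsilon fractional distance `delta_N/N` (negative for stability).
#' @export
f_near_neutral <- function(d_c, epsilon) {
  s <- perturbed_eigenvalues(d_c, epsilon)[1]
  if (Re(s) >= 0) stop("near-neutral estimate requires Re(s) < 0")
  q <- 2 + d_c$lam * d_c$xi_hat
  (2 * d_c$gamma * (d_c$lam - 1) * d_c$K_hat + d_c$lam * q) /
    (2 * d_c$K_hat * d_c$lam * q^2 * (-Re(s)))
}

#' Stationary spectrum matrix of the linear-noise model
#'
#' `S(omega) = (1/pi) * (i*omega - J*)^-1 D* (-i*omega - J*)^-T`, the
#' Fourier transform of the stationary time-correlation matrix; it
#' integrates to the stationary covariance, `sigma = integral S d(omega)`.
#' The `(3, 3)` component is the spindle-position spectrum;
#' `sqrt(S33)/omega_on` is the spectral amplitude in `z` units.
#'
#' @param J_star,D_star equilibrium Jacobian and correlation matrix
#'   (defaults from `d`).
#' @param omega angular-frequency grid; the default spans three decades
#'   around the resonant frequency.
#' @param d a `spindle_derived` object (used for defaults).
#' @return A list of class `noise_spectrum`: `omega`, `S` (3x3xlength
#'   complex array), `S33` (real vector), and `peak` (list with `omega`,
#'   `S33`, refined by golden-section search).
#' @export
noise_spectrum <- function(J_star = jacobian_star(d),
                           D_star = correlation_matrix_star(d),
                           omega = NULL, d = NULL) {
  ev <- eigen(J_star, only.values = TRUE)$values
  if (any(Re(ev) >= 0)) stop("spectrum requires a stable equilibrium")
  if (is.null(omega)) {
    Om_c <- max(abs(Im(ev)), 1)
    omega <- sort(unique(c(
      exp(seq(log(1e-3 * Om_c), log(1e2 * Om_c), length.out = 1024)),
      seq(0.25 * Om_c, 4 * Om_c, length.out = 1024))))
  }
  n <- nrow(J_star)
  S <- array(0i, c(n, n, length(omega)))
  for (i in seq_along(omega)) {
    R1 <- solve(1i * omega[i] * diag(n) - J_star)
    S[, , i] <- (1 / pi) * R1 %*% D_star %*% t(solve(-1i * omega[i] * diag(n)
                                                     - J_star))
  }
  S33 <- Re(S[n, n, ])
  s33_fun <- function(w) {
    R1 <- solve(1i * w * diag(n) - J_star)
    Re(((1 / pi) * R1 %*% D_star %*% t(solve(-1i * w * diag(n) -
                                               J_star)))[n, n])
  }
  ipk <- which.max(S33)
  lo <- omega[max(1, ipk - 1)]; hi <- omega[min(length(omega), ipk + 1)]
  opt <- stats::optimize(s33_fun, c(lo, hi), maximum = TRUE)
  structure(list(omega = omega, S = S, S33 = S33,
                 peak = list(omega = opt$maximum, S33 = opt$objective)),
            class = "noise_spectrum")
}

#' Integral of the spectrum matrix
#'
#' Componentwise adaptive quadrature of `S(omega)` over the whole frequency
#' axis; by the Wiener-Khinchin relation this recovers the stationary
#' covariance.
#'
#' @inheritParams noise_spectrum
#' @param rel_tol quadrature relative tolerance.
#' @return 3x3 matrix.
#' @export
spectrum_integral <- function(J_star, D_star, rel_tol = 1e-6) {
  n <- nrow(J_star)
  comp <- function(i, j) {
    fun <- function(w) {
      vapply(w, function(wk) {
        R1 <- solve(1i * wk * diag(n) - J_star)
        Re((R1 %*% D_star %*% t(solve(-1i * wk * diag(n) - J_star)))[i, j]) / pi
      }, 0)
    }
    stats::integrate(fun, -Inf, Inf, rel.tol = rel_tol,
                     subdivisions = 400L)$value
  }
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) out[i, j] <- out[j, i] <- comp(i, j)
  out
}

#' Euler-Maruyama simulation of the linear-noise SDE
#'
#' Simulates `dx = J* x dt + F dW` with `F` the symmetric square root of
#' `2 D*` and `W` a three-dimensional Wiener process (only `F F^T = 2 D*`
#' is constrained; a full-rank driving keeps the stated covariance
#' contract). The long-run empirical covariance approaches the Lyapunov
#' solution.
#'
#' @inheritParams noise_spectrum
#' @param t_end horizon in rescaled time.
#' @param dt Euler-Maruyama step.
#' @param seed optional RNG seed.
#' @param record_every thinning interval (in steps) of the returned path.
#' @param x0 initial deviation state.
#' @return A data frame with columns `t_tilde`, `B_plus`, `B_minus`,
#'   `z_tilde`.
#' @export
simulate_sde <- function(J_star = jacobian_star(d),
                         D_star = correlation_matrix_star(d),
                         t_end = 1e4, dt = 0.01, seed = NULL,
                         record_every = 10L, x0 = c(0, 0, 0), d = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(seed)) set.seed(seed)
  e <- eigen(2 * D_star, symmetric = TRUE)
  if (any(e$values < -1e-12)) stop("2 D* must be positive semidefinite")
  F_mat <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  nstep <- ceiling(t_end / dt)
  keep <- seq(1L, nstep, by = record_every)
  out <- matrix(0, length(keep), 3)
  x <- x0
  prop <- diag(3) + dt * J_star           # Euler drift propagator
  sq <- sqrt(dt)
  ki <- 1L
  for (s in seq_len(nstep)) {
    x <- prop %*% x + F_mat %*% (sq * stats::rnorm(3))
    if (ki <= length(keep) && s == keep[ki]) {
      out[ki, ] <- x
      ki <- ki + 1L
    }
  }
  data.frame(t_tilde = keep * dt, B_plus = out[, 1], B_minus = out[, 2],
             z_tilde = out[, 3])
}
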