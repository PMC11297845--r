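#' Uniform finite-volume grid on the extension axis
#'
#' @param M number of cells.
#' @param y_max domain length; cells cover `[0, y_max]` exactly with centres
#'   at `(j - 1/2) * h`, `h = y_max/M`.
#' @return A list of class `fp_grid` with `M`, `h`, cell centres `y` and
#'   face positions `y_face` (length `M + 1`).
#' @export
fp_grid <- function(M = 400, y_max = 6) {
  stopifnot(M >= 10, y_max > 1)
  h <- y_max / M
  structure(list(M = as.integer(M), h = h, y_max = y_max,
                 y = (seq_len(M) - 0.5) * h, y_face = (0:M) * h),
            class = "fp_grid")
}

#' Default initial densities for the mean-field model
#'
#' All probability starts unbound in a narrow normalised Gaussian
#' (`sigma = 2h`) against `y = 0`; bound densities start at zero, and the
#' spindle starts displaced (`z0 = 10` by default) to break the
#' cortex-exchange symmetry.
#'
#' @param grid an [fp_grid()].
#' @param z0 initial spindle position.
#' @return State vector `c(Pb+, Pb-, Pu+, Pu-, z)` of length `4M + 1`,
#'   normalised so each cortex carries unit probability.
#' @export
fp_initial_state <- function(grid, z0 = 10) {
  g <- exp(-0.5 * (grid$y / (2 * grid$h))^2)
  g <- g / (sum(g) * grid$h)
  c(rep(0, 2 * grid$M), g, g, z0)
}

#' Face fluxes of the extension-density equations
#'
#' First-order upwind advective part plus central diffusive part on cell
#' faces; the boundary faces at `y = 0` and `y = y_max` carry zero flux.
#' Bound advection velocity is `1 - y -/+ dz/dt`; unbound advection is
#' `-Gamma*y` with diffusivity `Gamma*D_u`.
#'
#' @param P density on cell centres.
#' @param v_face advection velocity evaluated on interior faces (length
#'   `M - 1`).
#' @param D diffusivity.
#' @param grid an [fp_grid()].
#' @return Numeric vector of fluxes on all `M + 1` faces.
#' @export
fp_fluxes <- function(P, v_face, D, grid) {
  M <- grid$M
  left <- P[-M]; right <- P[-1]
  adv <- ifelse(v_face > 0, v_face * left, v_face * right)
  c(0, adv - D * (right - left) / grid$h, 0)
}

#' Pulling force toward each cortex
#'
#' `F+- = N * integral of y * P_b+-(y, t) dy`, by midpoint quadrature.
#'
#' @param state full state vector (see [fp_initial_state()]).
#' @param grid an [fp_grid()].
#' @param N force generators per cortex.
#' @return `c(F_plus, F_minus)`.
#' @export
fp_pulling_force <- function(state, grid, N) {
  M <- grid$M
  Fp <- N * grid$h * sum(grid$y * state[1:M])
  Fm <- N * grid$h * sum(grid$y * state[(M + 1):(2 * M)])
  c(F_plus = Fp, F_minus = Fm)
}

#' Spindle force balance of the mean-field model
#'
#' `dz/dt = (-K*z - (F_minus - F_plus))/xi`.
#'
#' @inheritParams fp_pulling_force
#' @param p a `spindle_params` object.
#' @export
fp_spindle_rhs <- function(state, grid, p, N) {
  FF <- fp_pulling_force(state, grid, N)
  (-p$K * state[4 * grid$M + 1] - (FF[["F_minus"]] - FF[["F_plus"]])) / p$xi
}

# full semi-discrete RHS in deSolve's (t, y, parms) form; compiled kernel
fp_deriv <- function(t, state, parms) {
  list(fp_rhs_cpp(state, parms$M, parms$h, parms$y, parms$y_face,
                  parms$unbind, parms$K, parms$xi, parms$N,
                  parms$D_b, parms$D_u, parms$Gamma, parms$omega_on))
}

#' Integrate the mean-field Fokker-Planck model
#'
#' Advances the four coupled extension-density PDEs (finite-volume
#' semi-discretisation, first-order upwind advection, zero-flux boundaries)
#' together with the spindle force-balance ODE, using the stiff adaptive
#' integrator `lsodes` from \pkg{deSolve}. Total probability per cortex is
#' conserved bit-exactly by the discretisation; the reported drift measures
#' integrator error only.
#'
#' @param p a `spindle_params` object.
#' @param N force generators per cortex.
#' @param grid an [fp_grid()]; its `y_max` must match `p$y_max`.
#' @param t_end integration horizon (nondimensional time).
#' @param ics initial state vector; defaults to [fp_initial_state()].
#' @param sample_every output sampling interval.
#' @param snapshot_times times at which full density fields are stored.
#' @param rtol,atol integrator tolerances; tight defaults because period
#'   extraction differentiates small changes.
#' @param conservation_tol abort if per-cortex probability drifts by more
#'   than this.
#' @return A list of class `fp_solution`: `traj` (a `spindle_trajectory`
#'   data frame with `t`, `z`, peak locations `y_c_plus`, `y_c_minus` by
#'   parabolic interpolation and peak heights `P_max_plus`, `P_max_minus`),
#'   `snapshots` (list of data frames `y, P_b_plus, P_b_minus, P_u_plus,
#'   P_u_minus`), `conservation_drift`, `grid`, and the call parameters.
#' @export
#' @examples
#' \donttest{
#' p <- baseline_params(D_b = 8e-3, D_u = 4e-3)
#' sol <- run_fokker_planck(p, N = 15, grid = fp_grid(200), t_end = 500)
#' plot(sol$traj$t, sol$traj$z, type = "l")
#' }
run_fokker_planck <- function(p, N = p$N, grid = fp_grid(400, p$y_max),
                              t_end = 1e4, ics = fp_initial_state(grid),
                              sample_every = 2, snapshot_times = numeric(),
                              rtol = 1e-7, atol = 1e-9,
                              conservation_tol = 1e-4) {
  stopifnot(inherits(p, "spindle_params"), inherits(grid, "fp_grid"))
  if (abs(grid$y_max - p$y_max) > 1e-9)
    stop("grid y_max does not match parameter y_max")
  if (is.na(N) || N < 0) stop("N must be a non-negative integer")
  M <- grid$M
  mass0 <- vapply(1:2, function(s)
    sum(ics[c((s - 1) * M + 1:M, (s + 1) * M + 1:M)]) * grid$h, 0)
  if (any(abs(mass0 - 1) > 1e-6))
    stop("initial densities must carry unit probability per cortex")
  parms <- list(M = M, h = grid$h, y = grid$y, y_face = grid$y_face,
                unbind = p$omega_0 * exp(p$gamma * grid$y),
                K = p$K, xi = p$xi, N = N, D_b = p$D_b, D_u = p$D_u,
                Gamma = p$Gamma, omega_on = p$omega_on)
  times <- sort(unique(c(seq(0, t_end, by = sample_every), t_end,
                         snapshot_times)))
  out <- deSolve::ode(y = ics, times = times, func = fp_deriv, parms = parms,
                      method = "lsodes", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("stiff integration failed (istate = ", attr(out, "istate")[1], ")")
  state_mat <- out[, -1, drop = FALSE]
  tv <- out[, 1]

  # conservation per cortex at every sample
  mass <- sapply(1:2, function(s)
    rowSums(state_mat[, c((s - 1) * M + 1:M, (s + 1) * M + 1:M),
                      drop = FALSE]) * grid$h)
  drift <- max(abs(mass - 1))
  if (drift > conservation_tol)
    stop(sprintf(
      "probability conservation violated: drift %.3g exceeds %.3g",
      drift, conservation_tol))

  peak <- function(Pb) {
    # parabolic interpolation through the maximal cell and its neighbours
    j <- which.max(Pb)
    if (j == 1L || j == M)
      return(c(grid$y[j], Pb[j]))
    a <- Pb[j - 1]; b <- Pb[j]; c2 <- Pb[j + 1]
    denom <- a - 2 * b + c2
    dj <- if (abs(denom) > 1e-300) 0.5 * (a - c2) / denom else 0
    c(grid$y[j] + dj * grid$h, b - 0.25 * (a - c2) * dj)
  }
  pk_p <- t(apply(state_mat[, 1:M, drop = FALSE], 1, peak))
  pk_m <- t(apply(state_mat[, (M + 1):(2 * M), drop = FALSE], 1, peak))
  traj <- data.frame(t = tv, z = state_mat[, 4 * M + 1],
                     y_c_plus = pk_p[, 1], y_c_minus = pk_m[, 1],
                     P_max_plus = pk_p[, 2], P_max_minus = pk_m[, 2])
  attr(traj, "params") <- p
  attr(traj, "N") <- N
  attr(traj, "kind") <- "fokker_planck"
  class(traj) <- c("spindle_trajectory", "data.frame")

  snaps <- lapply(snapshot_times, function(ts) {
    i <- which.min(abs(tv - ts))
    data.frame(y = grid$y,
               P_b_plus = state_mat[i, 1:M],
               P_b_minus = state_mat[i, (M + 1):(2 * M)],
               P_u_plus = state_mat[i, (2 * M + 1):(3 * M)],
               P_u_minus = state_mat[i, (3 * M + 1):(4 * M)],
               t = tv[i])
  })
  structure(list(traj = traj, snapshots = snaps,
                 conservation_drift = drift, grid = grid, params = p, N = N),
            class = "fp_solution")
}
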