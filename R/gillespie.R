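#' Configuration for the event-driven stochastic simulator
#'
#' @param delta_y extension step of the discretised random walk; the default
#'   `y_max/120` resolves the diffusive peak widths at baseline diffusivities.
#' @param dt_max rate-refresh interval. The drift of bound walkers depends on
#'   the spindle velocity, which changes continuously between events, so
#'   frozen rates are refreshed at least this often; the default 0.01 is well
#'   below both the unbound retraction time `1/Gamma` and the spindle
#'   relaxation time `xi/K` at baseline.
#' @param t_end simulation horizon (nondimensional time).
#' @param z0 initial spindle position; nonzero by default to break the
#'   cortex-exchange symmetry.
#' @param record_every sampling interval of the recorded trajectory.
#' @return A list of class `gillespie_config`.
#' @export
gillespie_config <- function(delta_y = NULL, dt_max = 0.01, t_end = 1e4,
                             z0 = 10, record_every = 1) {
  stopifnot(dt_max > 0, t_end > 0, record_every > 0)
  structure(list(delta_y = delta_y, dt_max = dt_max, t_end = t_end,
                 z0 = z0, record_every = record_every),
            class = "gillespie_config")
}

#' Stochastic simulation of spindle-pole dynamics
#'
#' Event-driven (Gillespie) simulation of `2N` cortical force generators,
#' each a biased random walk on a discretised linker-extension axis with
#' binding-state switching, coupled to the overdamped spindle force balance.
#' Hop rates use a central splitting (`D/delta_y^2 +- v/(2*delta_y)`), which
#' reproduces the mean *and* variance of the target advection-diffusion
#' process exactly, with an upwind fallback wherever the central rates would
#' turn negative (`|v|*delta_y > 2*D`); boundaries at `y = 0` and `y = y_max` are reflecting (outward hop rate
#' zero). Bound walkers drift with `v = 1 - y -/+ dz/dt` and unbind at rate
#' `omega_0*exp(gamma*y)`; unbound walkers retract with `v = -Gamma*y`,
#' diffuse with `Gamma*D_u`, and bind at rate `omega_on`. All generators
#' start unbound at `y = 0`.
#'
#' Identical seeds give identical trajectories.
#'
#' @param p a `spindle_params` object.
#' @param N force generators per cortex (default `p$N`).
#' @param config a [gillespie_config()].
#' @param seed integer seed for R's RNG; `NULL` leaves the RNG state alone.
#' @return A `spindle_trajectory` data frame with columns `t`, `z`,
#'   per-cortex bound counts `n_b_plus`, `n_b_minus` and mean extensions
#'   `mean_yb_plus`, `mean_yb_minus`, `mean_yu_plus`, `mean_yu_minus`
#'   (`NA` where the corresponding population is empty).
#' @export
#' @examples
#' p <- baseline_params()
#' traj <- run_gillespie(p, N = 15, config = gillespie_config(t_end = 200),
#'                       seed = 1)
#' head(traj)
run_gillespie <- function(p, N = p$N, config = gillespie_config(),
                          seed = NULL) {
  stopifnot(inherits(p, "spindle_params"), inherits(config, "gillespie_config"))
  if (is.na(N) || N < 0) stop("N must be a non-negative integer")
  dy <- if (is.null(config$delta_y)) p$y_max / 120 else config$delta_y
  if (abs(p$y_max / dy - round(p$y_max / dy)) > 1e-8)
    stop("delta_y must divide y_max")
  if (!is.null(seed)) set.seed(seed)
  out <- gillespie_core(p$xi, p$K, p$omega_on, p$omega_0, p$y_max, p$gamma,
                        p$D_b, p$D_u, p$Gamma, as.integer(N), dy,
                        config$dt_max, config$t_end, config$z0,
                        config$record_every)
  traj <- as.data.frame(out)
  attr(traj, "params") <- p
  attr(traj, "N") <- N
  attr(traj, "kind") <- "gillespie"
  class(traj) <- c("spindle_trajectory", "data.frame")
  traj
}

#' Spindle velocity from a discrete generator ensemble
#'
#' The dimensionless force balance: `dz/dt = (-K*z + sum(y_b+) - sum(y_b-))/xi`
#' with the sums running over *bound* generators only.
#'
#' @param y_plus,y_minus numeric vectors of bound-linker extensions at the
#'   upper (+) and lower (-) cortex.
#' @param z spindle position.
#' @param p a `spindle_params` object.
#' @return The spindle velocity `dz/dt` (scalar).
#' @export
spindle_velocity <- function(y_plus, y_minus, z, p) {
  (-p$K * z + sum(y_plus) - sum(y_minus)) / p$xi
}

#' Drift velocities of bound and unbound generators
#'
#' Bound: `v = 1 - y -/+ dz/dt` (sign by cortex); unbound: `v = -Gamma*y`.
#'
#' @param y linker extension(s).
#' @param bound logical: bound or unbound.
#' @param cortex `+1` (upper) or `-1` (lower); ignored for unbound walkers.
#' @param dzdt current spindle velocity.
#' @param p a `spindle_params` object.
#' @export
drift_velocity <- function(y, bound, cortex = 1, dzdt = 0, p) {
  ifelse(bound, 1 - y - cortex * dzdt, -p$Gamma * y)
}

#' Event-rate table for a single generator
#'
#' Returns the frozen per-generator rates used by the simulator: hop-up and
#' hop-down rates from the upwinded splitting, and the binding/unbinding
#' rate for the current state. Hops that would leave `[0, y_max]` have rate
#' zero (reflecting boundaries).
#'
#' @inheritParams drift_velocity
#' @param delta_y extension step.
#' @return Named numeric vector `c(hop_up, hop_down, switch)` where `switch`
#'   is the unbinding rate (bound) or binding rate (unbound).
#' @export
event_rates <- function(y, bound, cortex = 1, dzdt = 0, p,
                        delta_y = p$y_max / 120) {
  v <- drift_velocity(y, bound, cortex, dzdt, p)
  D <- if (bound) p$D_b else p$Gamma * p$D_u
  base <- D / delta_y^2
  if (base >= abs(v) / (2 * delta_y)) {       # central: both moments exact
    up <- base + v / (2 * delta_y)
    dn <- base - v / (2 * delta_y)
  } else {                                    # upwind fallback
    up <- base + max(v, 0) / delta_y
    dn <- base + max(-v, 0) / delta_y
  }
  if (y >= p$y_max - 1e-12) up <- 0
  if (y <= 1e-12) dn <- 0
  sw <- if (bound) p$omega_0 * exp(p$gamma * y) else p$omega_on
  c(hop_up = up, hop_down = dn, switch = sw)
}

#' Moments of the free biased random walk used by the simulator
#'
#' Simulates `nsamp` independent unbounded walkers with the simulator's
#' hop-rate construction at constant drift `v` and diffusivity `D`, and
#' returns their displacements at `t_end`. The sample mean should approach
#' `v*t_end` and the sample variance `2*D*t_end`.
#'
#' @param nsamp number of independent walkers.
#' @param v constant drift velocity.
#' @param D diffusivity.
#' @param delta_y extension step.
#' @param t_end walk duration.
#' @param seed optional RNG seed.
#' @return Numeric vector of displacements.
#' @export
walker_moment_sample <- function(nsamp, v, D, delta_y, t_end, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  walker_displacements(as.integer(nsamp), v, D, delta_y, t_end)
}
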