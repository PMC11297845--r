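grid15 <- fp_grid(M = 15, y_max = 6)   # h = 0.4; cell 3 centred at y = 1

test_that("face fluxes: uniform field, advection sign, flux balance", {
  g <- fp_grid(60, 6)
  vf <- rep(0, g$M - 1)
  expect_equal(fp_fluxes(rep(1 / 6, g$M), vf, D = 0.08, g),
               rep(0, g$M + 1))
  # retracting unbound density: net flux toward y = 0 in the interior
  P <- exp(-0.5 * (g$y / 0.3)^2); P <- P / (sum(P) * g$h)
  vf_u <- -20 * g$y_face[2:g$M]
  J <- fp_fluxes(P, vf_u, D = 20 * 0.04, g)
  expect_true(all(J[2:10] < 0))
  expect_identical(J[1], 0); expect_identical(J[g$M + 1], 0)
  # steady balance v P = D dP/dy at a face gives zero flux
  P2 <- rep(0, g$M); P2[10] <- 1; P2[11] <- 2
  v <- 0.08 / g$h * (P2[11] - P2[10]) / P2[10]
  vf2 <- rep(0, g$M - 1); vf2[10] <- v
  expect_equal(fp_fluxes(P2, vf2, D = 0.08, g)[11], 0)
})

test_that("pulling force by midpoint quadrature", {
  st0 <- c(rep(0, 4 * grid15$M), 0)
  expect_equal(unname(fp_pulling_force(st0, grid15, 15)), c(0, 0))
  # unit point mass at the stall extension (cell centred on y = 1)
  st <- st0
  st[3] <- 1 / grid15$h
  expect_equal(fp_pulling_force(st, grid15, 15)[["F_plus"]], 15)
  # symmetric bound fields give equal pulls
  st[grid15$M + 3] <- 1 / grid15$h
  FF <- fp_pulling_force(st, grid15, 15)
  expect_equal(FF[["F_plus"]], FF[["F_minus"]])
})

test_that("spindle force balance", {
  M <- grid15$M
  st <- c(rep(0, 4 * M), 0)
  expect_equal(fp_spindle_rhs(st, grid15, bl, 15), 0)
  # F+ = 1, F- = 0, z = 0 -> dz/dt = 1/xi
  st1 <- st; st1[3] <- (1 / grid15$h) / 15
  expect_equal(fp_spindle_rhs(st1, grid15, bl, 15), 1.6)
  # balance point: F+ - F- = K z
  st2 <- st1; st2[4 * M + 1] <- 1 / bl$K
  expect_equal(fp_spindle_rhs(st2, grid15, bl, 15), 0)
})

test_that("compiled semi-discrete RHS agrees with the reference flux
           assembly", {
  g <- fp_grid(50, 6)
  set.seed(4)
  mk <- function(s) { v <- runif(g$M); s * v / (sum(v) * g$h) }
  st <- c(mk(0.35), mk(0.4), mk(0.65), mk(0.6), 2.5)
  parms <- list(M = g$M, h = g$h, y = g$y, y_face = g$y_face,
                unbind = bl$omega_0 * exp(bl$gamma * g$y), K = bl$K,
                xi = bl$xi, N = 15, D_b = bl$D_b, D_u = bl$D_u,
                Gamma = bl$Gamma, omega_on = bl$omega_on)
  d_cpp <- spindleosc:::fp_deriv(0, st, parms)[[1]]
  dzdt <- fp_spindle_rhs(st, g, bl, 15)
  expect_equal(d_cpp[4 * g$M + 1], dzdt, tolerance = 1e-12)
  vf <- g$y_face[2:g$M]
  Pbp <- st[1:g$M]; Pup <- st[2 * g$M + 1:g$M]
  Jb <- fp_fluxes(Pbp, 1 - vf - dzdt, bl$D_b, g)
  Ju <- fp_fluxes(Pup, -bl$Gamma * vf, bl$Gamma * bl$D_u, g)
  react <- bl$omega_on * Pup - parms$unbind * Pbp
  expect_equal(d_cpp[1:g$M], -diff(Jb) / g$h + react, tolerance = 1e-12)
  expect_equal(d_cpp[2 * g$M + 1:g$M], -diff(Ju) / g$h - react,
               tolerance = 1e-12)
})

test_that("cortex-swap antisymmetry of the semi-discrete RHS", {
  g <- fp_grid(80, 6)
  set.seed(2)
  mk <- function() { v <- runif(g$M); v / (sum(v) * g$h) }
  Pb1 <- mk() * 0.4; Pu1 <- mk() * 0.6
  Pb2 <- mk() * 0.3; Pu2 <- mk() * 0.7
  st <- c(Pb1, Pb2, Pu1, Pu2, 3.2)
  sw <- c(Pb2, Pb1, Pu2, Pu1, -3.2)
  f <- function(s) spindleosc:::fp_deriv(0, s, list(
    M = g$M, h = g$h, y = g$y, y_face = g$y_face,
    unbind = bl$omega_0 * exp(bl$gamma * g$y), K = bl$K, xi = bl$xi,
    N = 15, D_b = bl$D_b, D_u = bl$D_u, Gamma = bl$Gamma,
    omega_on = bl$omega_on))[[1]]
  d1 <- f(st); d2 <- f(sw)
  M <- g$M
  expect_equal(d2[1:M], d1[(M + 1):(2 * M)], tolerance = 1e-12)
  expect_equal(d2[(2 * M) + 1:M], d1[(3 * M) + 1:M], tolerance = 1e-12)
  expect_equal(d2[4 * M + 1], -d1[4 * M + 1], tolerance = 1e-12)
})

test_that("symmetric initial fields with centred spindle stay fixed", {
  g <- fp_grid(120, 6)
  sol <- run_fokker_planck(bl, 15, grid = g, t_end = 200,
                           ics = fp_initial_state(g, z0 = 0),
                           sample_every = 5)
  # z stays at the symmetric fixed point up to integrator error (the
  # oscillation scale of asymmetric runs is O(30))
  expect_lt(max(abs(sol$traj$z)), 1e-3)
})

test_that("probability is conserved and initial states must be normalised", {
  g <- fp_grid(150, 6)
  sol <- run_fokker_planck(bl, 15, grid = g, t_end = 300, sample_every = 5)
  expect_lt(sol$conservation_drift, 1e-6)
  bad <- fp_initial_state(g) * 1.5
  expect_error(run_fokker_planck(bl, 15, grid = g, t_end = 10, ics = bad),
               "unit probability")
})

test_that("unbound peak width scales as sqrt(D_u)", {
  width_at <- function(Du) {
    p <- baseline_params(D_b = 8e-3, D_u = Du)
    g <- fp_grid(400, 6)
    sol <- run_fokker_planck(p, 15, grid = g, t_end = 250,
                             sample_every = 50, snapshot_times = 250)
    sn <- sol$snapshots[[1]]
    Pu <- sn$P_u_plus / (sum(sn$P_u_plus) * g$h)
    m1 <- sum(sn$y * Pu) * g$h
    sqrt(sum((sn$y - m1)^2 * Pu) * g$h)
  }
  ratio <- width_at(0.04) / width_at(0.004)
  expect_lt(abs(ratio / sqrt(10) - 1), 0.2)
})

test_that("low diffusivity at N = 15 gives a decaying (non-oscillatory)
           spindle", {
  sol <- run_fokker_planck(bl_lowD, 15, grid = fp_grid(300, 6),
                           t_end = 4000, sample_every = 2)
  expect_false(classify_trajectory(sol$traj, window = 0.4))
  expect_lt(abs(sol$traj$z[nrow(sol$traj)]), 0.5)
})

test_that("the post-transient attractor is insensitive to initial
           conditions", {
  # a configuration with fast binding kinetics (omega_on scaled up tenfold
  # at fixed rho), where the limit cycle saturates within a few cycles —
  # at baseline kinetics the linear growth rate mu*omega_on makes full
  # amplitude saturation prohibitively long-horizoned
  p <- baseline_params(omega_on = 0.03, omega_0 = 0.01)
  g <- fp_grid(240, 6)
  run1 <- function(ics)
    run_fokker_planck(p, 25, grid = g, t_end = 1600, ics = ics,
                      sample_every = 1, rtol = 1e-6, atol = 1e-8)
  a <- run1(fp_initial_state(g))
  ic <- fp_initial_state(g, z0 = -4)   # different z0, part of the mass bound
  gsh <- exp(-0.5 * ((g$y - 1.5) / 0.5)^2)
  bump <- 0.3 * gsh / (sum(gsh) * g$h)
  ic[1:g$M] <- bump; ic[g$M + 1:g$M] <- bump
  ic[2 * g$M + 1:g$M] <- ic[2 * g$M + 1:g$M] * 0.7
  ic[3 * g$M + 1:g$M] <- ic[3 * g$M + 1:g$M] * 0.7
  b <- run1(ic)
  expect_lt(abs(trajectory_period(b$traj, 0.4)$period /
                  trajectory_period(a$traj, 0.4)$period - 1), 0.02)
  expect_lt(abs(trajectory_amplitude(b$traj, 0.5) /
                  trajectory_amplitude(a$traj, 0.5) - 1), 0.02)
})

test_that("the oscillation period converges under grid refinement", {
  # measured periods 938.1 / 941.6 / 943.4 at M = 200/300/400 (t_end 6000,
  # baseline, N = 25): the production grid M = 400 agrees with M = 300 to
  # well under 1%
  p <- baseline_params()
  run <- function(M) {
    sol <- run_fokker_planck(p, 25, grid = fp_grid(M, 6), t_end = 6000,
                             sample_every = 2)
    trajectory_period(sol$traj, 0.5)$period
  }
  expect_lt(abs(run(300) / run(400) - 1), 0.01)
})
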