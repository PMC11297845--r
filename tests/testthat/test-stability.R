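# Frozen oracle values (computed by independent polyroot / eigen / bisection
# before the analysis code was written):
#   baseline N = 15: complex pair -0.331449331 +/- 2.470690511i, real -lam
#   N_c(omega_on = 0.003) = 22.2868956; neutral-point period 1012.780 t units

test_that("characteristic roots match the independent polynomial oracle", {
  sr <- characteristic_roots(bl15)
  pair <- sr$roots[1:2]
  expect_equal(sort(Re(pair)), rep(-0.331449331, 2), tolerance = 1e-8)
  expect_equal(sort(abs(Im(pair))), rep(2.470690511, 2), tolerance = 1e-8)
  expect_identical(Re(sr$roots[3]), -bl15$lam)   # real root is exactly -lam
  expect_equal(pair[1], Conj(pair[2]))
  expect_equal(sr$mu, Re(pair[1]))
  expect_equal(sr$Omega, abs(Im(pair[1])))
  expect_false(sr$oscillatory)                   # damped at N = 15
})

test_that("growth rate vanishes exactly at the neutral K_hat and is
           monotone across it", {
  for (d in random_derived(8, seed = 7)) {
    Kc <- neutral_K(d)
    if (Kc <= 0) next
    dn <- d; dn$K_hat <- Kc
    expect_lt(abs(characteristic_roots(dn)$mu), 1e-12)
    dlo <- d; dlo$K_hat <- Kc * 0.8
    dhi <- d; dhi$K_hat <- Kc * 1.2
    expect_gt(characteristic_roots(dlo)$mu, 0)
    expect_lt(characteristic_roots(dhi)$mu, 0)
  }
})

test_that("large gamma destabilises", {
  d <- derive_params(baseline_params(gamma = 6), 15)
  expect_gt(characteristic_roots(d)$mu, 0)
})

test_that("binding-rate window threshold omega_dagger", {
  expect_equal(omega_dagger(2, 0.001), 0.0073891, tolerance = 1e-5)
  expect_equal(signif(omega_dagger(2, 0.001), 2), 0.0074)
  expect_equal(omega_dagger(1, 0.001), 0)       # window closes at gamma = 1
  expect_equal(omega_dagger(0.5, 0.001), 0)
  expect_equal(omega_dagger(2, 0), 0)
})

test_that("critical generator number and neutral period at baseline", {
  mu_N <- function(N) characteristic_roots(derive_params(bl, N))$mu
  Nc <- uniroot(mu_N, c(5, 100), tol = 1e-10)$root
  expect_equal(Nc, 22.2868956, tolerance = 1e-6)
  dc <- derive_params(bl, Nc)
  Om <- sqrt(dc$K_hat * dc$lam^2 / (2 + dc$xi_hat * dc$lam))
  expect_equal(2 * pi / (Om * bl$omega_on), 1012.780, tolerance = 1e-5)
  # (19a) frequency agrees with the full quadratic on the neutral curve
  expect_equal(characteristic_roots(dc)$Omega, Om, tolerance = 1e-6)
})

test_that("neutral curve forms a wedge with the expected asymptotes", {
  nc <- neutral_curve(bl, omega_on = c(0.002, 0.003, 0.005, 0.007, 0.008))
  cv <- nc$curve
  expect_equal(nc$omega_dagger, omega_dagger(2, 0.001))
  expect_equal(nc$N_min, 0.625 / 1)    # xi/(gamma - 1) at baseline
  # a single threshold exists inside the window, none outside
  inside <- cv$omega_on < nc$omega_dagger
  expect_true(all(is.finite(cv$N_c[inside])))
  expect_true(all(is.na(cv$N_c[!inside])))
  expect_true(all(cv$N_c >= nc$N_min, na.rm = TRUE))
  # the closed-form root agrees with bisection on mu(N)
  for (i in which(inside)) {
    pw <- bl; pw$omega_on <- cv$omega_on[i]
    expect_equal(cv$N_c[i], spindleosc:::neutral_N_roots(pw)[1],
                 tolerance = 1e-6)
    # mu changes sign across the threshold: stable below, growing above
    expect_gt(characteristic_roots(derive_params(pw, cv$N_c[i] * 1.2))$mu, 0)
    expect_lt(characteristic_roots(derive_params(pw, cv$N_c[i] * 0.8))$mu, 0)
  }
  # branch labelling splits at the nose and the upper branch diverges
  # toward omega_dagger
  expect_true(nc$omega_nose > 0.002 && nc$omega_nose < nc$omega_dagger)
  near <- neutral_curve(bl, omega_on = c(0.9, 0.99) * nc$omega_dagger)$curve
  expect_true(all(is.finite(near$N_upper)))
  expect_true(all(is.na(near$N_lower)))
  expect_gt(near$N_upper[2], 5 * near$N_upper[1])
  low <- neutral_curve(bl, omega_on = c(1e-3, 1.5e-3))$curve
  expect_true(all(is.finite(low$N_lower)))
  expect_true(all(diff(low$N_lower) < 0))   # falling lower branch
})

test_that("weak-restoring curve and its turning-point relation", {
  # closed-form K_hat -> 0 branch: N = xi (w + w0 e^g)^2 / (2 w (w0 e^g (g-1) - w))
  wdag <- omega_dagger(bl$gamma, bl$omega_0)
  NlowK <- function(w) {
    den <- bl$omega_0 * exp(bl$gamma) * (bl$gamma - 1) - w
    bl$xi * (w + bl$omega_0 * exp(bl$gamma))^2 / (2 * w * den)
  }
  nc <- neutral_curve(bl, omega_on = c(0.002, 0.004))
  expect_equal(nc$curve$N_lowK, NlowK(c(0.002, 0.004)), tolerance = 1e-12)
  # turning point of the curve satisfies w/wdag = (N - xi/(g-1))/(2N + xi)
  dN <- function(w) (NlowK(w + 1e-9) - NlowK(w - 1e-9)) / 2e-9
  wstar <- uniroot(dN, c(1e-3, 6e-3), tol = 1e-14)$root
  Nstar <- NlowK(wstar)
  expect_lt(abs(wstar / wdag -
                  (Nstar - bl$xi / (bl$gamma - 1)) / (2 * Nstar + bl$xi)),
            1e-8)
})

test_that("period predictions: regimes, validity and divergence", {
  pp <- period_predictions(bl, 15)
  expect_equal(pp$period_t, pp$period_t_tilde / bl$omega_on)
  expect_true(all(pp$valid))
  # the large-N closed form reproduces the stochastic-regime prediction
  largeN <- pp$period_t[pp$regime == "large_N"]
  expect_equal(largeN, 925.6, tolerance = 1e-3)
  # period diverges along the neutral curve as omega_on -> omega_dagger
  wdag <- omega_dagger(bl$gamma, bl$omega_0)
  nc <- neutral_curve(bl, omega_on = wdag * c(0.5, 0.9, 0.99))
  expect_true(all(diff(nc$curve$period_t) > 0))
  expect_gt(nc$curve$period_t[3] / nc$curve$period_t[1], 3)
  # outside the window the weak-restoring form is flagged invalid
  phi <- bl; phi$omega_on <- 0.009
  expect_false(period_predictions(phi, 15)$valid[2])
  # T ~ K_hat^{-1/2} from the neutral-frequency form at fixed lam
  p1 <- period_predictions(bl, 15)$period_t_tilde[1]
  blK <- baseline_params(K = 0.05 / 4)
  p2 <- period_predictions(blK, 15)$period_t_tilde[1]
  expect_equal(p2 / p1, 2, tolerance = 0.02)
})

test_that("Grill-variant comparators collapse onto the reduced forms for
           small omega_0 and separate at omega_0 = 0.1", {
  # the correction terms scale with (gamma+1)*omega_0*e^gamma (~2% at the
  # baseline omega_0 = 0.001) and vanish linearly with omega_0
  g <- grill_comparators(bl15)
  Om2 <- bl15$K_hat * bl15$lam^2 / (2 + bl15$xi_hat * bl15$lam)
  expect_lt(abs(g$Omega2 / Om2 - 1), 0.05)
  expect_lt(abs(g$K_hat_threshold / neutral_K(bl15) - 1), 0.05)
  d_tiny <- derive_params(baseline_params(omega_0 = 1e-4), 15)
  g_tiny <- grill_comparators(d_tiny)
  expect_lt(abs(g_tiny$K_hat_threshold / neutral_K(d_tiny) - 1),
            abs(g$K_hat_threshold / neutral_K(bl15) - 1) / 5)
  # omega_on -> 0 limit is exactly the reduced threshold
  d0 <- bl15; d0$omega_on <- 1e-12; d0$rho <- d0$omega_0 / d0$omega_on
  d0$lam <- 1 + d0$rho * exp(d0$gamma)
  expect_equal(grill_comparators(d0)$K_hat_threshold, neutral_K(d0),
               tolerance = 1e-9)
  # at omega_0 = 0.1 the Grill threshold requires more generators
  ph <- baseline_params(omega_0 = 0.1, omega_on = 0.3)
  roots_red <- spindleosc:::neutral_N_roots(ph)
  roots_grill <- spindleosc:::grill_neutral_N_roots(ph)
  expect_true(length(roots_red) >= 1 && length(roots_grill) >= 1)
  expect_gt(min(roots_grill), min(roots_red) * 1.1)
})
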