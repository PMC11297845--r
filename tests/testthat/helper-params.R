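# shared fixtures: baseline parameter objects used across test files
bl <- baseline_params()
bl15 <- derive_params(bl, 15)
bl25 <- derive_params(bl, 25)

# low-diffusivity variant used for the mean-field stability comparisons
bl_lowD <- baseline_params(D_b = 8e-3, D_u = 4e-3)

# random derived-parameter draws (stable or not), reproducible
random_derived <- function(n, seed = 42, stable = NA) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    p <- spindle_params(xi = runif(1, 0.1, 2), K = runif(1, 0.01, 0.5),
                        omega_on = runif(1, 5e-4, 8e-3),
                        omega_0 = runif(1, 2e-4, 3e-3),
                        y_max = 6, gamma = runif(1, 1.2, 3),
                        D_b = 0.08, D_u = 0.04, Gamma = 20)
    N <- sample(5:60, 1)
    d <- derive_params(p, N)
    if (!is.na(stable)) {
      mu <- characteristic_roots(d)$mu
      if (stable && mu >= -1e-6) next
      if (!stable && mu <= 1e-6) next
    }
    out[[length(out) + 1L]] <- d
  }
  out
}
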