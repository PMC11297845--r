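Package: spindleosc
Title: Relaxation and Noise-Driven Oscillations of the Mitotic Spindle Pole
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of one-dimensional mitotic spindle-pole dynamics driven by
    cortical force generators (dynein motors on elastic linkers) opposed by a
    microtubule restoring force. Provides an event-driven stochastic simulator
    of 2N binding/unbinding force generators treated as biased random walks on
    a linker-extension axis, a mean-field Fokker-Planck solver for the coupled
    extension-density equations, the asymptotically reduced three-variable ODE
    system together with its linear stability analysis (growth rates, neutral
    curves, period predictions) and relaxation-oscillation structure, and a
    linear-noise characterisation of noise-induced oscillations (stationary
    covariance via the Lyapunov equation, power spectra, and Euler-Maruyama
    simulation). Includes trajectory analysis utilities (period, amplitude,
    occupation-time-weighted interquartile range, oscillation classification)
    and generators of synthetic test traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
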