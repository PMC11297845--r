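---
title: "Models of spindle-pole oscillations driven by cortical force generators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of spindle-pole oscillations driven by cortical force generators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindleosc)
```

## The model

During metaphase the mitotic spindle is positioned by astral microtubules
that reach from the spindle poles to the cell cortex. Cortically anchored
force generators — dynein motors tethered by elastic linkers — bind these
microtubules and pull the pole toward their cortex, while microtubule
dynamic instability and bending supply a centring (restoring) force. In many
systems the pole does not settle quietly: it oscillates, sometimes with the
jagged sawtooth structure of a relaxation oscillation, sometimes as a noisy,
weakly coherent wobble.

`spindleosc` implements a one-dimensional model of this tug of war at four
levels of description, from individual stochastic force generators to a
three-variable ODE and its analytic theory.

**Force balance.** The pole position $z(t)$ (nondimensionalised on the stall
length $y_0 = f_0/k_g$ and stall time $y_0/v_0$) obeys the overdamped
balance
$$\xi \frac{dz}{dt} = -K z + \sum_n y^{(n)+}_b - \sum_n y^{(n)-}_b,$$
where the sums run over linkers currently *bound* at the upper ($+$) and
lower ($-$) cortex and $y$ is a linker extension. Bound motors walk with
velocity $v_b^\pm = 1 - y \mp dz/dt$ (linear force–velocity with stall at
$y = 1$), unbound linkers retract with $v_u = -\Gamma y$. Binding occurs at
constant rate $\omega_{on}$; unbinding is a slip bond, at rate
$\omega_0 e^{\gamma y}$. Slip-bond behaviour, $\gamma > 1$, is what makes
sustained oscillation possible: extension of the loaded population triggers
its collective release.

**Levels of description.**

1. `run_gillespie()` — an event-driven simulation of the $2N$ generators as
   biased random walks on a discretised extension axis (diffusivities $D_b$,
   $\Gamma D_u$) with stochastic binding-state switching, coupled to the
   force balance. This retains both noise sources: motion of generators and
   binding kinetics.
2. `run_fokker_planck()` — the mean-field model: four advection–diffusion–
   reaction PDEs for the extension densities $P^\pm_{b}$, $P^\pm_{u}$ with
   no-flux boundaries, coupled to the force balance through
   $F^\pm = N \int y P^\pm_b\,dy$. Binding kinetics are deterministic here;
   only generator motion is stochastic (via the diffusive terms).
3. `integrate_reduced()` — the slow-binding asymptotic reduction
   ($\omega_{on} \sim \omega_0 \sim \sqrt{D_b} \sim \sqrt{D_u} \ll 1$) to
   three ODEs for $(\tilde z, \hat B^+, \hat B^-)$, where $\hat B^\pm$
   tracks the bound-density peak amplitude and the peak location follows
   $y_c^\pm = 1 \mp \tilde z_{\tilde t}$. `integrate_grill()` provides the
   earlier heuristic variant with an implicitly defined typical detachment
   extension; the two coincide as $\omega_0 \to 0$.
4. `characteristic_roots()`, `neutral_curve()`, `relaxation_amplitude()`,
   and the `noise_*`/`solve_lyapunov()` family — the analytic layer: linear
   stability and neutral curves in the $(N, \omega_{on})$ plane, the
   small-$\hat K$ relaxation-oscillation structure through the
   displacement–velocity function $G$, and the linear-noise (Lyapunov /
   spectrum / SDE) theory of noise-induced oscillations in the linearly
   stable regime.

## Parameters

Nondimensional parameters (constructed by `baseline_params()`, derived from
dimensional estimates by `nondimensionalize()`):

| name | meaning | baseline |
|------|---------|---------:|
| `xi` | pole drag relative to stall force at speed $v_0$ | 0.625 |
| `K`  | restoring stiffness / linker stiffness | 0.05 |
| `omega_on` | binding rate × stall time | 0.003 |
| `omega_0` | unbinding coefficient × stall time | 0.001 |
| `y_max` | maximum extension in stall lengths | 6 |
| `gamma` | slip-bond tension sensitivity | 2 |
| `D_b`, `D_u` | bound/unbound tip diffusivities | 0.08, 0.04 |
| `Gamma` | unbound retraction rate / stall rate | 20 |
| `N` | generators per cortex | caller-set |

The printed baselines take precedence over values recomputed from the
dimensional table: recomputation gives, e.g., $\xi = 0.6$ and
$\gamma = 2.1$, consistent to within 10% but not identical, and all
reference figures use the baseline column. The dimensional unbound
diffusivity maps to `D_u` through `D_u_bar/(y0*v0*Gamma)`, because the
unbound flux carries the product $\Gamma D_u$; this is the one loosely
pinned parameter (the dimensional estimate lands ~11% from the declared
0.04). Temperature is not modelled.

The reduced model depends only on `derive_params()`: the binding affinity
$\rho = \omega_0/\omega_{on}$, per-capita drag $\hat\xi = \xi/N$ and
stiffness $\hat K = K/(N\omega_{on})$, and $\lambda = 1 + \rho e^\gamma$.

## Numerical choices

**Stochastic simulator.** Extensions are discretised with
$\Delta y = y_{max}/120$ by default. Hop rates use a *central* splitting,
$D/\Delta y^2 \pm v/(2\Delta y)$, which reproduces the mean **and** the
variance of the target advection–diffusion process exactly; wherever the
central rates would turn negative ($|v|\Delta y > 2D$, mainly unbound
linkers far from the cortex) the construction falls back to first-order
upwind, whose $O(\Delta y)$ excess variance is then negligible relative to
the local advection. A pure upwind splitting would inflate the bound-linker
variance by $|v|\Delta y \approx 30\%$ of $2 D_b$ at the default step and
visibly bias stochastic amplitudes; the free-walker moment test
(`walker_moment_sample()`) guards the construction. Between events the
force balance is linear in $z$ (extensions frozen), so $z$ advances by the
exact exponential update. Because the bound drift depends on $dz/dt$,
frozen rates are refreshed at least every `dt_max = 0.01` (well inside
$1/\Gamma$ and $\xi/K$); the freeze is the declared approximation — there
is no exact thinning of time-varying rates. All generators start unbound at
$y = 0$ and the pole starts displaced (`z0 = 10`) to break the
cortex-exchange symmetry; one seeded generator drives the whole run, so
identical seeds give identical trajectories.

**Mean-field solver.** Finite-volume semi-discretisation on a uniform grid
(`M = 400` cells by default) with first-order upwind advection and central
diffusion; the unbound equation is strongly advection-dominated
($\Gamma = 20$), where a central advective flux would oscillate at feasible
resolutions. Boundary faces carry exactly zero flux, so per-cortex
probability is conserved bit-exactly by the scheme and any reported drift
(aborted above $10^{-4}$, observed near $10^{-7}$) measures integrator
error. Time stepping uses the stiff sparse solver `lsodes` (deSolve) at
`rtol = 1e-7`, `atol = 1e-9` — period extraction needs tight tolerances;
classification-only runs in the test-suite relax these to `1e-6/1e-8`. A
grid-refinement test checks the period at M = 300 against the production
grid M = 400 to 1% (the sparse solver's factorisation cost grows steeply
beyond M ≈ 500, which bounds practical refinement upward). Initial
densities place all mass in a narrow unbound Gaussian ($\sigma = 2h$)
against $y = 0$ with `z0 = 10`; a dedicated test confirms the
post-transient attractor is insensitive to these choices. Bound-peak
locations are read off by parabolic interpolation through the maximal cell.

**Reduced and Grill ODEs.** The reduced velocity equation is solved
explicitly for $\tilde z_{\tilde t}$ (no DAE machinery). In the Grill
variant the velocity equation and the two implicit typical-extension
equations are mutually consistent roots; because the velocity residual is
strictly monotone in the velocity and each extension equation is monotone
in $y$, both are solved by safeguarded bracketed iteration (`uniroot`, to
$10^{-12}$), nested rather than by damped fixed-point iteration — bracketing
cannot diverge and needs no damping heuristics. Default initial conditions
displace $\tilde z$ by 0.1 and detune $\hat B^\pm$ from the fixed point
$1/\lambda$ by $\pm 10^{-3}$.

**Trajectory analysis.** Periods are measured as the mean spacing of upward
zero-crossings, which is robust for strongly non-sinusoidal relaxation
waveforms where a spectral peak would sit among harmonics. Two safeguards
make crossings robust for noisy records: a hysteresis band (half-width
0.25 sd) so that a crossing only counts after a full excursion below and
above the band, and a zero-phase running-mean pre-smoothing one tenth of
the dominant periodogram timescale wide, which leaves crossing intervals of
periodic signals untouched. "Oscillatory" means: the final-window standard
deviation exceeds `max(1e-3, 0.05 × initial-window sd)` *and* the final
window contains at least 3 hysteresis-filtered upward crossings. These
thresholds are declared conventions (none of the model levels defines
"sustained" sharply) and are validated against the linear-stability
classification; for expensive mean-field classification runs the tests use
a half-record window with a 2-crossing floor so that a 6000-t-unit run
spans enough cycles. The occupation-time-weighted IQR weights each sample
by its holding time, making it insensitive to the recording interval.

**Linear-noise layer.** The stationary covariance solves the Lyapunov
equation via the Kronecker-vectorised linear system; the printed 6×6
coefficient system and the closed-form $z$-variance are kept as independent
cross-checks and agree to $10^{-8}$ relative. The SDE uses Euler–Maruyama
with the symmetric square root of $2D^*$ driving three independent Wiener
components — only $FF^\top = 2D^*$ is constrained by the theory, and a
full-rank driving realises the covariance contract exactly.

## What the synthetic generator does and does not emulate

`make_fixture()` produces sine, relaxation (asymmetric sawtooth), decaying,
and noisy-sine traces with known ground truth; they exercise the period,
classification and IQR estimators, not the physics. The simulators
themselves are the physical data generators. None of these emulate real
imaging data: experimental tracks are two-dimensional, drift-contaminated,
and short (tens of cycles at best), so passing tests demonstrate estimator
correctness on the model's own output, not readiness for raw microscopy
tracks (no drift removal or 2-D preprocessing is provided).

## Study conditions and problem sizes

The quantitative tests and `scripts/acceptance.R` use desk-scale versions
of the reference configurations: mean-field periods at $N = 25$ with
$M = 400$ over horizons of 9,000–10,500 t-units (periods measured on the
final 40%); stochastic IQRs at $N = 15$ and $18$ over $10^4$ t-units × 3
seeds (first half discarded); the neutral-curve cross-validation at six
$(N, \omega_{on})$ points with $M = 240$ over 6,000 t-units. The
noise-induced-oscillation period is compared against the linear-noise
spectral peak (its theoretically appropriate comparator for a noise-driven
damped resonator) rather than the neutral-point period, within 25%.

## Known limitations

* One dimension, linear restoring force, no cell boundary: relaxation
  amplitudes at small $\hat K$ can exceed any realistic cell size; the
  model is a mechanism study, not a cell-scale digital twin.
* The mean-field level treats binding deterministically, so it misses the
  noise-induced oscillations that the stochastic level shows in the
  linearly stable regime — that discrepancy is the point of the
  linear-noise layer, which in turn is a small-amplitude theory whose
  near-neutral variance estimate diverges at the curve and is best read as
  an upper bound.
* First-order upwind advection in the mean-field solver adds $O(h)$
  numerical diffusion; at the default grid this is ~9% of $D_b$ at
  baseline diffusivities and proportionally more at the tenfold-reduced
  setting, which is why the grid-convergence test guards the period.
* The Gillespie rate-freeze between refreshes is an $O(dt_{max})$
  approximation, controlled but not eliminated by `dt_max = 0.01`.
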