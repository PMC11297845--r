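#' Coerce a two-column time series to a spindle trajectory
#'
#' @param t,z sampling times (strictly increasing) and positions.
#' @param kind label stored on the object.
#' @return A `spindle_trajectory` data frame.
#' @export
as_spindle_trajectory <- function(t, z, kind = "external") {
  stopifnot(length(t) == length(z), all(diff(t) > 0))
  traj <- data.frame(t = t, z = z)
  attr(traj, "kind") <- kind
  class(traj) <- c("spindle_trajectory", "data.frame")
  traj
}

# Upward zero-crossing times of the mean-subtracted signal, by linear
# interpolation between samples. A hysteresis band of half-width
# `hysteresis * sd(z)` suppresses the spurious crossings that measurement or
# binding noise creates while the signal hovers near zero: a crossing is
# counted only once the signal has visited below -h and then above +h, and
# is timed at the last interpolated zero crossing of that excursion.
# Exact for clean periodic signals (whose excursions dwarf the band).
upward_crossings <- function(t, z, hysteresis = 0.25) {
  z <- z - mean(z)
  h <- hysteresis * stats::sd(z)
  if (!is.finite(h)) return(numeric())
  if (h == 0) {
    i <- which(z[-length(z)] < 0 & z[-1] >= 0)
    if (!length(i)) return(numeric())
    return(t[i] + (t[i + 1] - t[i]) * (-z[i]) / (z[i + 1] - z[i]))
  }
  st <- ifelse(z > h, 1L, ifelse(z < -h, -1L, 0L))
  nz <- which(st != 0L)
  if (length(nz) < 2L) return(numeric())
  flip <- which(diff(st[nz]) == 2L)        # below -h, next outside band is +h
  vapply(flip, function(k) {
    seg <- nz[k]:(nz[k + 1L] - 1L)
    j <- seg[z[seg] < 0 & z[seg + 1L] >= 0]
    j <- j[length(j)]
    t[j] + (t[j + 1L] - t[j]) * (-z[j]) / (z[j + 1L] - z[j])
  }, 0)
}

window_rows <- function(traj, from_frac, to_frac) {
  t0 <- traj$t[1]; t1 <- traj$t[nrow(traj)]
  lo <- t0 + from_frac * (t1 - t0)
  hi <- t0 + to_frac * (t1 - t0)
  which(traj$t >= lo & traj$t <= hi)
}

#' Classify a trajectory as oscillatory or decaying
#'
#' A trajectory is classed oscillatory when the standard deviation of `z`
#' over the final window exceeds `max(tol_abs, rel * sd(initial window))`
#' *and* the final window contains at least `min_crossings` upward
#' zero-crossings. The thresholds are declared conventions (the underlying
#' models provide no sharp definition of "sustained"); they are validated
#' against the linear-stability classification in the package tests.
#'
#' @param traj a `spindle_trajectory`.
#' @param window fraction of the record used for the initial and final
#'   comparison windows.
#' @param tol_abs absolute floor on the final-window standard deviation.
#' @param rel relative decay threshold against the initial window.
#' @param min_crossings minimum upward zero-crossings in the final window.
#' @param hysteresis half-width of the crossing-detection hysteresis band,
#'   in units of the window standard deviation.
#' @return Logical flag.
#' @export
#' @examples
#' classify_trajectory(make_fixture("sine", period = 100, t_end = 1000))
#' classify_trajectory(make_fixture("decaying", tau = 100))
classify_trajectory <- function(traj, window = 0.2, tol_abs = 1e-3,
                                rel = 0.05, min_crossings = 3L,
                                hysteresis = 0.25) {
  if (nrow(traj) < 10) stop("trajectory too short to classify")
  if (window <= 0 || window > 0.5) stop("window must lie in (0, 0.5]")
  ini <- window_rows(traj, 0, window)
  fin <- window_rows(traj, 1 - window, 1)
  if (length(fin) < 5L || length(ini) < 5L)
    stop("trajectory too short to classify")
  sd_fin <- stats::sd(traj$z[fin])
  sd_ini <- stats::sd(traj$z[ini])
  nc <- length(upward_crossings(traj$t[fin], traj$z[fin], hysteresis))
  isTRUE(sd_fin > max(tol_abs, rel * sd_ini)) && nc >= min_crossings
}

# dominant period of the (uniformly resampled) signal from a smoothed
# periodogram; NA when no interior spectral peak stands out
dominant_period_psd <- function(t, z) {
  dt <- stats::median(diff(t))
  tu <- seq(t[1], t[length(t)], by = dt)
  zu <- stats::approx(t, z, xout = tu)$y
  sp <- try(stats::spec.pgram(stats::ts(zu - mean(zu), deltat = dt),
                              spans = c(5, 5), detrend = TRUE, taper = 0.1,
                              plot = FALSE), silent = TRUE)
  if (inherits(sp, "try-error")) return(NA_real_)
  1 / sp$freq[which.max(sp$spec)]
}

#' Oscillation period from upward zero-crossings
#'
#' Mean spacing of upward zero-crossings of the mean-subtracted signal over
#' the post-transient window. Zero-crossing timing (rather than the spectral
#' peak itself) is robust for strongly non-sinusoidal relaxation waveforms.
#' For noisy records two safeguards are applied: crossings are counted with
#' a hysteresis band (see `hysteresis`), and the signal is first low-passed
#' with a centred running mean one-tenth of the dominant periodogram
#' timescale wide — a zero-phase linear filter, so crossing *intervals* of a
#' periodic signal are unaffected while sample-to-sample noise is strongly
#' suppressed.
#'
#' @param traj a `spindle_trajectory`.
#' @param transient_fraction fraction of the record discarded as transient
#'   (0.3 is appropriate for deterministic runs, 0.5 for stochastic ones).
#' @param hysteresis crossing-detection band half-width in units of the
#'   window standard deviation; suppresses noise-induced spurious crossings.
#' @param smooth logical: apply the periodogram-guided pre-smoothing.
#' @return A list with `period` (mean crossing interval), `sd` (dispersion
#'   of the intervals) and `n_crossings`.
#' @export
trajectory_period <- function(traj, transient_fraction = 0.3,
                              hysteresis = 0.25, smooth = TRUE) {
  rows <- window_rows(traj, transient_fraction, 1)
  t <- traj$t[rows]; z <- traj$z[rows]
  if (smooth) {
    Tpsd <- dominant_period_psd(t, z)
    dt <- stats::median(diff(t))
    w <- floor(Tpsd / 10 / dt)
    if (is.finite(w) && w >= 2) {
      zs <- stats::filter(z, rep(1 / w, w), sides = 2)
      ok <- !is.na(zs)
      t <- t[ok]; z <- as.numeric(zs[ok])
    }
  }
  cr <- upward_crossings(t, z, hysteresis)
  if (length(cr) < 3L)
    stop("fewer than 3 upward zero-crossings in the analysis window")
  iv <- diff(cr)
  list(period = mean(iv), sd = stats::sd(iv), n_crossings = length(cr))
}

#' Mean peak-to-trough half-amplitude
#'
#' Splits the post-transient window at its upward zero-crossings and
#' averages half the (max - min) range over complete cycles.
#'
#' @inheritParams trajectory_period
#' @export
trajectory_amplitude <- function(traj, transient_fraction = 0.3) {
  rows <- window_rows(traj, transient_fraction, 1)
  t <- traj$t[rows]; z <- traj$z[rows]
  cr <- upward_crossings(t, z)
  if (length(cr) < 2L) return((max(z) - min(z)) / 2)
  cyc <- findInterval(t, cr)
  keep <- cyc >= 1 & cyc < length(cr)
  if (!any(keep)) return((max(z) - min(z)) / 2)
  ranges <- tapply(z[keep], cyc[keep], function(v) (max(v) - min(v)) / 2)
  mean(ranges)
}

#' Occupation-time-weighted interquartile range of position
#'
#' The interquartile range of `z` where each sample is weighted by its
#' holding time (piecewise-constant occupation between records); used as an
#' amplitude summary for noisy trajectories. Insensitive to the recording
#' interval.
#'
#' @inheritParams trajectory_period
#' @export
#' @examples
#' traj <- make_fixture("noisy", period = 900, amplitude = 50, snr = 5,
#'                      seed = 1)
#' weighted_iqr(traj, transient_fraction = 0.5)
weighted_iqr <- function(traj, transient_fraction = 0.5) {
  rows <- window_rows(traj, transient_fraction, 1)
  t <- traj$t[rows]; z <- traj$z[rows]
  if (length(z) < 2L) stop("post-transient window is empty")
  w <- diff(t)
  z <- z[-length(z)]
  o <- order(z)
  z <- z[o]; w <- w[o]
  cw <- (cumsum(w) - w / 2) / sum(w)
  q <- stats::approx(cw, z, xout = c(0.25, 0.75), rule = 2)$y
  q[2] - q[1]
}

#' Periodogram of the post-transient window
#'
#' Smoothed periodogram (via [stats::spec.pgram()]) of the detrended,
#' uniformly resampled post-transient signal; a spectral cross-check of the
#' zero-crossing period.
#'
#' @inheritParams trajectory_period
#' @param spans smoothing spans passed to [stats::spec.pgram()].
#' @return Data frame with `freq` (cycles per time unit) and `spec`.
#' @export
trajectory_psd <- function(traj, transient_fraction = 0.5, spans = NULL) {
  rows <- window_rows(traj, transient_fraction, 1)
  t <- traj$t[rows]; z <- traj$z[rows]
  dt <- stats::median(diff(t))
  tu <- seq(t[1], t[length(t)], by = dt)
  zu <- stats::approx(t, z, xout = tu)$y
  sp <- stats::spec.pgram(stats::ts(zu - mean(zu), deltat = dt),
                          spans = spans, detrend = TRUE, plot = FALSE,
                          taper = 0.1)
  data.frame(freq = sp$freq, spec = sp$spec)
}

#' Full trajectory analysis
#'
#' Bundles classification, period, amplitude, weighted IQR and periodogram.
#'
#' @inheritParams trajectory_period
#' @param window classification window fraction (see
#'   [classify_trajectory()]).
#' @return A list of class `trajectory_analysis` with fields `oscillatory`,
#'   `period`, `period_sd`, `amplitude`, `iqr`, `psd`.
#' @export
analyze_trajectory <- function(traj, transient_fraction = 0.5,
                               window = 0.2) {
  osc <- classify_trajectory(traj, window = window)
  per <- tryCatch(trajectory_period(traj, transient_fraction),
                  error = function(e) list(period = NA_real_, sd = NA_real_))
  structure(list(oscillatory = osc,
                 period = per$period, period_sd = per$sd,
                 amplitude = trajectory_amplitude(traj, transient_fraction),
                 iqr = weighted_iqr(traj, transient_fraction),
                 psd = trajectory_psd(traj, transient_fraction)),
            class = "trajectory_analysis")
}

#' @export
print.trajectory_analysis <- function(x, ...) {
  cat(sprintf(
    "Trajectory analysis: %s; period = %s, amplitude = %.4g, IQR = %.4g\n",
    if (x$oscillatory) "oscillatory" else "non-oscillatory",
    ifelse(is.na(x$period), "n/a", format(x$period, digits = 5)),
    x$amplitude, x$iqr))
  invisible(x)
}

#' Synthetic test trajectories
#'
#' Deterministic or seeded traces with known ground truth, used as fixtures:
#' `"sine"` (pure sinusoid), `"relaxation"` (asymmetric triangle wave with
#' near-linear drift phases and rapid reversals), `"decaying"` (exponential
#' decay), `"noisy"` (sinusoid plus white noise of amplitude
#' `amplitude/snr`).
#'
#' @param kind one of `"sine"`, `"relaxation"`, `"decaying"`, `"noisy"`.
#' @param period,amplitude oscillation parameters.
#' @param tau decay timescale (`"decaying"` only).
#' @param z0 initial amplitude of the decaying trace.
#' @param snr signal-to-noise ratio (`"noisy"` only).
#' @param t_end,dt sampling horizon and interval.
#' @param seed RNG seed for the noisy trace.
#' @param phase phase offset (radians) of the oscillatory kinds.
#' @return A `spindle_trajectory`.
#' @export
make_fixture <- function(kind = c("sine", "relaxation", "decaying", "noisy"),
                         period = 100, amplitude = 5, tau = 100, z0 = 10,
                         snr = 5, t_end = 10 * period, dt = period / 200,
                         seed = NULL, phase = 0) {
  kind <- match.arg(kind)
  t <- seq(0, t_end, by = dt)
  z <- switch(kind,
    sine = amplitude * sin(2 * pi * t / period + phase),
    relaxation = {
      # slow linear drift (90% of the cycle) with a rapid reversal
      u <- ((t / period + phase / (2 * pi)) %% 1)
      tri <- ifelse(u < 0.9, -1 + 2 * u / 0.9, 1 - 2 * (u - 0.9) / 0.1)
      amplitude * tri
    },
    decaying = z0 * exp(-t / tau),
    noisy = {
      if (!is.null(seed)) set.seed(seed)
      amplitude * sin(2 * pi * t / period + phase) +
        stats::rnorm(length(t), sd = amplitude / snr)
    })
  as_spindle_trajectory(t, z, kind = paste0("fixture_", kind))
}
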