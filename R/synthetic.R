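# Seeded generators for every input the analysis consumes: PMT-like tissue
# records (damped ~24 h oscillation, slow trend, Gaussian or shot-like
# noise, kcpm scale), paired left/right tissue designs driven by the coupled
# chain model, developmental (age, period) series, phase-map fixtures, and
# locomotor-style event series.

#' Generate a synthetic bioluminescence tissue record
#'
#' Emulates a photomultiplier recording of a tissue explant: a damped
#' sinusoid of given period and amplitude (kcpm) on a baseline with a slow
#' linear trend, sampled every `dt_h` hours, plus additive Gaussian noise
#' (SD a fixed fraction of the amplitude) or shot-like noise (SD scaling
#' with the square root of the instantaneous signal).
#'
#' @param period_h Oscillation period (h).
#' @param amplitude_kcpm Initial oscillation amplitude in kcpm (the tissue
#'   operating range is roughly 20-150 kcpm).
#' @param damping_per_h Exponential amplitude decay rate (1/h).
#' @param baseline_kcpm Constant baseline level.
#' @param trend_kcpm_per_h Linear baseline drift.
#' @param noise `"gaussian"` or `"shot"`.
#' @param noise_sd Gaussian noise SD as a fraction of `amplitude_kcpm`
#'   (gaussian mode) or the shot-noise scale factor (shot mode).
#' @param days,dt_h Record length (days) and sampling interval (h).
#' @param phase0_rad Phase at time zero.
#' @param seed Optional seed; identical seeds give identical records.
#' @param tissue,side,condition,age_days Design metadata columns.
#' @return Tibble: `time_h`, `signal_kcpm`, `tissue`, `side`, `condition`,
#'   `age_days`.
#' @export
synth_tissue_record <- function(period_h = 24, amplitude_kcpm = 80,
                                damping_per_h = 0.005, baseline_kcpm = 100,
                                trend_kcpm_per_h = -0.1,
                                noise = c("gaussian", "shot"), noise_sd = 0.03,
                                days = 12, dt_h = 0.25, phase0_rad = 0,
                                seed = NULL, tissue = "synthetic", side = NA,
                                condition = "control", age_days = NA) {
  noise <- match.arg(noise)
  if (!is.null(seed)) withr::local_seed(seed)
  t <- seq(0, days * 24 - dt_h, by = dt_h)
  clean <- baseline_kcpm + trend_kcpm_per_h * t +
    amplitude_kcpm * exp(-damping_per_h * t) *
    cos(2 * pi * t / period_h - phase0_rad)
  eps <- switch(noise,
    gaussian = stats::rnorm(length(t), 0, noise_sd * amplitude_kcpm),
    shot = stats::rnorm(length(t), 0, noise_sd * sqrt(pmax(clean, 0)))
  )
  tibble::tibble(time_h = t, signal_kcpm = pmax(clean + eps, 0),
                 tissue = tissue, side = side, condition = condition,
                 age_days = age_days)
}

# integrate a chain (possibly split into independent pieces) and return the
# ensemble-mean x as a record-like tibble
chain_ensemble_record <- function(tau, phi0, q, K, amplitude, lambda, twist,
                                  days, dt, pieces = 1) {
  n <- length(tau)
  bounds <- floor(seq(0, n, length.out = pieces + 1))
  sigs <- lapply(seq_len(pieces), function(pc) {
    idx <- (bounds[pc] + 1):bounds[pc + 1]
    if (length(idx) == 1) {
      p <- osc_params(amplitude, lambda, twist, tau[idx])
      traj <- integrate_oscillator(p, r0 = amplitude, phi0 = phi0[idx],
                                   t_end = days * 24, dt = dt)
    } else {
      spec <- chain_network(length(idx), K = K, q = q, amplitude = amplitude,
                            lambda = lambda, twist = twist, period = tau[idx])
      traj <- simulate_network(spec, days = days, dt = dt,
                               init = tibble::tibble(x = amplitude * cos(phi0[idx]),
                                                     y = amplitude * sin(phi0[idx])))
    }
    ensemble_signal(traj, mode = "sum")
  })
  out <- sigs[[1]]
  if (pieces > 1) {
    for (k in 2:pieces) out$signal <- out$signal + sigs[[k]]$signal
  }
  out$signal <- out$signal / n
  out
}

#' Generate a paired left/right tissue design from the chain model
#'
#' The bilaterally symmetric tissue gives a natural paired design: both sides
#' share the same seeded draw of intrinsic periods and initial phases; the
#' control side is simulated at full coupling and the test side under a
#' manipulation - a reduced coupling multiplier (gap-junction blockade) or a
#' cut into `cuts` independent sub-chains (surgical dissection; no coupling
#' across cuts).
#'
#' @param n Chain length per side.
#' @param q_control,q_test Coupling multipliers for the two sides.
#' @param cuts Number of pieces the test side is cut into (1 = intact).
#' @param days,dt_h Simulation length and sampling.
#' @param K Coupling constant; default [calibrate_coupling()].
#' @param period_mean,period_sd,phase_sd_h Parameter draw settings.
#' @inheritParams chain_network
#' @param seed Seed fixing the shared intrinsic parameter draw.
#' @return List of class `paired_design`: `control` and `test` (tibbles
#'   `time_h`, `signal`), plus the manipulation settings.
#' @export
synth_paired_design <- function(n = 60, q_control = 10, q_test = 10, cuts = 1,
                                days = 12, dt_h = 0.25, K = NULL,
                                amplitude = 1, lambda = 0.02, twist = -0.01,
                                period_mean = 25.5, period_sd = 1,
                                phase_sd_h = 1, seed = 1) {
  stopifnot(cuts >= 1, cuts <= n)
  if (is.null(K)) K <- calibrate_coupling(lambda = lambda, twist = twist,
                                          period = period_mean)
  tau <- draw_periods(n, period_mean, period_sd, seed = seed)
  withr::with_seed(seed + 10000L, {
    phi0 <- 2 * pi * stats::rnorm(n, 0, phase_sd_h) / tau
  })
  ctl <- chain_ensemble_record(tau, phi0, q_control, K, amplitude, lambda,
                               twist, days, dt_h, pieces = 1)
  tst <- chain_ensemble_record(tau, phi0, q_test, K, amplitude, lambda,
                               twist, days, dt_h, pieces = cuts)
  structure(list(control = ctl, test = tst, n = n, q_control = q_control,
                 q_test = q_test, cuts = cuts, seed = seed),
            class = "paired_design")
}

#' Compare the two sides of a paired design
#'
#' @param design A `paired_design`.
#' @param discard_h Transient discarded before estimation (h).
#' @param days RMS window (days).
#' @return One-row tibble: `period_control_h`, `period_test_h`,
#'   `period_diff_h` (test - control), `rms_control`, `rms_test`, `rms_ratio`
#'   (test / control).
#' @export
compare_pair <- function(design, discard_h = 48, days = 10) {
  stopifnot(inherits(design, "paired_design"))
  one <- function(rec) {
    rec <- rec[rec$time_h >= discard_h, ]
    days_avail <- min(days, floor((max(rec$time_h) - min(rec$time_h)) / 24))
    tibble::tibble(period = estimate_period(rec)$period_h,
                   rms = rms_amplitude(rec, days = days_avail))
  }
  a <- one(design$control); b <- one(design$test)
  tibble::tibble(period_control_h = a$period, period_test_h = b$period,
                 period_diff_h = b$period - a$period,
                 rms_control = a$rms, rms_test = b$rms,
                 rms_ratio = b$rms / a$rms)
}

#' Generate a synthetic developmental (age, period) table
#'
#' Periods follow the exponential maturation curve
#' `period = a * exp(-age/tau_c) + c` (defaults: a = 1.58 h, tau_c = 9.47
#' days, c = 23.41 h) plus Gaussian noise.
#'
#' @param ages Postnatal ages in days.
#' @param a,tau_c,c0 Curve parameters (h, days, h).
#' @param noise_sd Gaussian noise SD (h).
#' @param n_per_age Replicates per age.
#' @param seed Optional seed.
#' @return Tibble: `age_days`, `period_h`.
#' @export
synth_development <- function(ages = c(0, 7, 14, 21, 28, 100), a = 1.58,
                              tau_c = 9.47, c0 = 23.41, noise_sd = 0.2,
                              n_per_age = 10, seed = NULL) {
  stopifnot(all(ages >= 0))
  if (!is.null(seed)) withr::local_seed(seed)
  t <- rep(ages, each = n_per_age)
  tibble::tibble(
    age_days = t,
    period_h = a * exp(-t / tau_c) + c0 + stats::rnorm(length(t), 0, noise_sd)
  )
}

#' Generate a synthetic phase map
#'
#' Fixture patterns for spatial statistics: a smooth `"gradient"` (linear in
#' position along the longest axis, spanning `gradient_span` radians),
#' spatially `"random"` phases (uniform on the circle), or an alternating
#' two-phase `"checkerboard"`. Circular Gaussian noise of SD `noise_sd` is
#' added and wrapped.
#'
#' @param nrow,ncol Map dimensions; `nrow = 1` gives a chain.
#' @param pattern `"gradient"`, `"random"` or `"checkerboard"`.
#' @param noise_sd Wrapped Gaussian noise SD (rad).
#' @param gradient_span Total phase span of the gradient (rad).
#' @param seed Optional seed.
#' @return A `phase_map`.
#' @export
synth_phase_map <- function(nrow = 1, ncol = 20,
                            pattern = c("gradient", "random", "checkerboard"),
                            noise_sd = 0, gradient_span = 1, seed = NULL) {
  pattern <- match.arg(pattern)
  if (!is.null(seed)) withr::local_seed(seed)
  g <- expand.grid(row = seq_len(nrow), col = seq_len(ncol))
  n <- base::nrow(g)
  base_phase <- switch(pattern,
    gradient = {
      pos <- if (ncol >= nrow) g$col else g$row
      gradient_span * (pos - 1) / max(pos - 1)
    },
    random = stats::runif(n, 0, 2 * pi),
    # two alternating phases pi/2 apart: a defined circular mean (exactly
    # antipodal phases would have zero resultant) with maximal negative
    # neighbour correlation of the deviations
    checkerboard = pi / 4 + (pi / 2) * ((g$row + g$col) %% 2)
  )
  ph <- base_phase + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  as_phase_map(tibble::tibble(row = g$row, col = g$col,
                              phase_rad = ph %% (2 * pi)))
}

#' Generate a locomotor-style event series
#'
#' Counts per `bin_h`-hour bin from an inhomogeneous Poisson process:
#' `"rhythmic"` series alternate between a high rate during the active
#' fraction of each cycle and a low rate otherwise; `"flat"` series are
#' homogeneous Poisson (the null for periodogram calibration).
#'
#' @param period_h Activity period (h).
#' @param days Length in days (>= 7 for periodogram use).
#' @param bin_h Bin width (h).
#' @param activity_fraction Fraction of the cycle at the high rate.
#' @param rate_high,rate_low Expected counts per bin in/out of the active bout.
#' @param pattern `"rhythmic"` or `"flat"` (flat uses `rate_low` throughout).
#' @param seed Optional seed.
#' @return Tibble: `bin_start_h`, `count`.
#' @export
synth_event_series <- function(period_h = 23.7, days = 10, bin_h = 0.1,
                               activity_fraction = 0.5, rate_high = 5,
                               rate_low = 0.2,
                               pattern = c("rhythmic", "flat"), seed = NULL) {
  pattern <- match.arg(pattern)
  if (!is.null(seed)) withr::local_seed(seed)
  t <- seq(0, days * 24 - bin_h, by = bin_h)
  lambda <- if (pattern == "flat") {
    rep(rate_low, length(t))
  } else {
    phase <- (t %% period_h) / period_h
    ifelse(phase < activity_fraction, rate_high, rate_low)
  }
  tibble::tibble(bin_start_h = t, count = stats::rpois(length(t), lambda))
}
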