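#' Single-cell twist oscillator parameters
#'
#' The modified Poincare oscillator describes a cellular circadian clock by a
#' stable limit cycle of radius `amplitude`, approached at radial relaxation
#' rate `lambda`, rotating with angular velocity `omega = 2*pi/period`. The
#' `twist` parameter couples instantaneous amplitude to instantaneous angular
#' velocity: `dphi/dt = omega + twist * (amplitude - r)`. A negative twist
#' means that an amplitude excess (r above the steady-state radius) transiently
#' speeds the oscillation up.
#'
#' @param amplitude Steady-state radius of the limit cycle (dimensionless, > 0).
#' @param lambda Radial relaxation rate in 1/h (> 0).
#' @param twist Twist (shear) parameter in 1/h; may be negative, zero or positive.
#' @param period Intrinsic free-running period in hours (> 0).
#'
#' @return An object of class `osc_params`: a list with elements `amplitude`,
#'   `lambda`, `twist`, `period` and the derived `omega` (rad/h).
#' @examples
#' p <- osc_params()                # A = 1, lambda = 0.02/h, twist = -0.01/h, 24 h
#' p$omega * p$period / (2 * pi)   # exactly 1
#' @export
osc_params <- function(amplitude = 1, lambda = 0.02, twist = -0.01, period = 24) {
  stopifnot(
    is.numeric(amplitude), length(amplitude) == 1L, amplitude > 0,
    is.numeric(lambda), length(lambda) == 1L, lambda > 0,
    is.numeric(twist), length(twist) == 1L, is.finite(twist),
    is.numeric(period), length(period) == 1L, period > 0
  )
  structure(
    list(amplitude = amplitude, lambda = lambda, twist = twist,
         period = period, omega = 2 * pi / period),
    class = "osc_params"
  )
}

#' @export
print.osc_params <- function(x, ...) {
  cat("<osc_params> A =", x$amplitude, " lambda =", x$lambda,
      "/h  twist =", x$twist, "/h  period =", x$period, "h\n")
  invisible(x)
}

#' Vector field of the twist oscillator in polar coordinates
#'
#' Radial dynamics `dr/dt = lambda * r * (A - r)` and phase dynamics
#' `dphi/dt = omega + twist * (A - r)`. The origin `r = 0` is a valid
#' (unstable) fixed point of the radial equation.
#'
#' @param params An [osc_params()] object.
#' @param r Radius (>= 0); vectorised.
#' @param phi Phase in radians; vectorised (recycled against `r`). The field
#'   does not depend on `phi`; it is accepted for interface symmetry.
#'
#' @return A tibble with columns `r`, `phi`, `dr_dt`, `dphi_dt`.
#' @export
poincare_field <- function(params, r, phi = 0) {
  stopifnot(inherits(params, "osc_params"), all(r >= 0))
  n <- max(length(r), length(phi))
  r <- rep_len(r, n); phi <- rep_len(phi, n)
  tibble::tibble(
    r = r, phi = phi,
    dr_dt = params$lambda * r * (params$amplitude - r),
    dphi_dt = params$omega + params$twist * (params$amplitude - r)
  )
}

#' Closed-form radial solution
#'
#' `r(t) = A / (exp(-lambda*A*t) * (A/r0 - 1) + 1)`: monotone relaxation of the
#' radius from `r0 > 0` towards the limit-cycle amplitude `A`.
#'
#' @param params An [osc_params()] object.
#' @param r0 Initial radius (> 0; the closed form is singular at 0).
#' @param t Time(s) in hours; vectorised.
#' @return Numeric vector of radii.
#' @export
radial_solution <- function(params, r0, t) {
  stopifnot(inherits(params, "osc_params"))
  if (!is.numeric(r0) || length(r0) != 1L || r0 <= 0) {
    stop("`r0` must be a single positive radius; the closed form is degenerate at r0 <= 0.")
  }
  A <- params$amplitude
  A / (exp(-params$lambda * A * t) * (A / r0 - 1) + 1)
}

#' Closed-form phase solution (unwrapped)
#'
#' `phi(t) = phi0 + omega*t + twist*A*t +
#'   (twist/lambda) * log( (A/r0) / (A/r0 - 1 + exp(lambda*A*t)) )`.
#' Reduces to `phi0 + omega*t` on the limit cycle (`r0 = A`) and for zero
#' twist. The returned phase is cumulative (unwrapped).
#'
#' @inheritParams radial_solution
#' @param phi0 Initial phase in radians.
#' @return Numeric vector of unwrapped phases (rad).
#' @export
phase_solution <- function(params, r0, phi0, t) {
  stopifnot(inherits(params, "osc_params"))
  if (!is.numeric(r0) || length(r0) != 1L || r0 <= 0) {
    stop("`r0` must be a single positive radius; the closed form is degenerate at r0 <= 0.")
  }
  A <- params$amplitude; lam <- params$lambda; eps <- params$twist
  phi0 + params$omega * t + eps * A * t +
    (eps / lam) * log((A / r0) / (A / r0 - 1 + exp(lam * A * t)))
}

#' Asymptotic phase (isochron label) of a state
#'
#' The isochron through `(r0, phi0)` is labelled by the phase this state
#' converges to on the limit cycle: `phi0 + (twist/lambda) * log(A/r0)`.
#' Without twist the isochrons are straight radial lines and the asymptotic
#' phase equals `phi0` for every radius.
#'
#' @inheritParams phase_solution
#' @return Asymptotic phase in radians (same wrapping convention as `phi0`).
#' @export
asymptotic_phase <- function(params, r0, phi0 = 0) {
  stopifnot(inherits(params, "osc_params"))
  if (!is.numeric(r0) || any(r0 <= 0)) {
    stop("`r0` must be positive; the isochron label has a log singularity at r0 = 0.")
  }
  phi0 + (params$twist / params$lambda) * log(params$amplitude / r0)
}

# unwrap a wrapped phase sequence to a cumulative one
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  phi[1] + c(0, cumsum(d))
}

#' Integrate a single twist oscillator numerically
#'
#' Integrates the oscillator in Cartesian coordinates (the polar form is
#' singular at the origin) with `deSolve::ode` (lsoda), at tolerances tight
#' enough to out-resolve the closed-form solutions. `r0 = 0` is allowed: it is
#' a fixed point of the dynamics.
#'
#' @param params An [osc_params()] object.
#' @param r0,phi0 Initial polar state (`r0 >= 0`).
#' @param t_end End time in hours.
#' @param dt Output sampling interval in hours (> 0).
#' @param rtol,atol Integrator tolerances.
#' @return A tibble of class `twist_trajectory` with columns `time_h`,
#'   `oscillator`, `x`, `y`, `r`, `phase_rad` (unwrapped).
#' @export
integrate_oscillator <- function(params, r0 = params$amplitude, phi0 = 0,
                                 t_end = 240, dt = 0.25,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "osc_params"), r0 >= 0, dt > 0, is.finite(t_end))
  spec <- new_network_spec(
    n = 1L, topology = "single",
    coupling = matrix(0, 1, 1), q = 0L,
    params = tibble::tibble(
      oscillator = 1L, amplitude = params$amplitude, lambda = params$lambda,
      twist = params$twist, period_h = params$period, omega = params$omega
    ),
    geometry = tibble::tibble(oscillator = 1L, row = 1L, col = 1L)
  )
  simulate_network(spec, t_end = t_end, dt = dt,
                   init = tibble::tibble(x = r0 * cos(phi0), y = r0 * sin(phi0)),
                   rtol = rtol, atol = atol)
}
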