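# Shared fixtures and independent oracles.

default_params <- function(twist = -0.01, period = 24) {
  osc_params(amplitude = 1, lambda = 0.02, twist = twist, period = period)
}

# Independent oracle: integrate the oscillator in POLAR coordinates (the
# package integrates Cartesian), valid for r0 > 0.
polar_oracle <- function(params, r0, phi0, times, rtol = 1e-10, atol = 1e-12) {
  f <- function(t, y, p) {
    list(c(params$lambda * y[1] * (params$amplitude - y[1]),
           params$omega + params$twist * (params$amplitude - y[1])))
  }
  sol <- deSolve::ode(c(r = r0, phi = phi0), times, f, NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  list(r = sol[, "r"], phi = sol[, "phi"])
}

wrap_pi <- function(x) atan2(sin(x), cos(x))

# Five-seed default chain simulation used by several acceptance checks.
# Computed lazily once per test run.
chain_sim_cache <- new.env(parent = emptyenv())
default_chain_sims <- function(seeds = 1:5, q = 10, n = 60, days = 12) {
  key <- paste(c(seeds, q, n, days), collapse = "_")
  if (is.null(chain_sim_cache[[key]])) {
    chain_sim_cache[[key]] <- lapply(seeds, function(s) {
      tau <- draw_periods(n, 25.5, 1, seed = s)
      phi0 <- withr::with_seed(s + 10000L, 2 * pi * stats::rnorm(n, 0, 1) / tau)
      spec <- chain_network(n, q = q, period = tau)
      traj <- simulate_network(spec, days = days,
                               init = tibble::tibble(x = cos(phi0), y = sin(phi0)))
      list(seed = s, tau = tau, spec = spec, traj = traj)
    })
  }
  chain_sim_cache[[key]]
}

ensemble_period <- function(traj, discard_h = 48) {
  sig <- ensemble_signal(traj)
  estimate_period(sig[sig$time_h >= discard_h, ])$period_h
}
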