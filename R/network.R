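# Coupled twist-oscillator networks: 1D chains with open boundaries,
# 2D von Neumann / radius / masked grids, mean-field predictions, and the
# dose-response sweep over the coupling multiplier q.

new_network_spec <- function(n, topology, coupling, q, params, geometry) {
  structure(
    list(n = as.integer(n), topology = topology, coupling = coupling,
         q = q, params = params, geometry = geometry),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>", x$topology, "of", x$n, "oscillators, q =", x$q,
      "\n  mean intrinsic period:", round(mean(x$params$period_h), 3), "h",
      " twist:", x$params$twist[1], "/h\n")
  invisible(x)
}

#' Calibrate the nearest-neighbour coupling constant from the mean field
#'
#' Inverts the mean-field frequency shift `omega' = omega - twist * K_i / lambda`
#' for an interior chain cell (`K_i = 2 * q * K`) so that the synchronized
#' ensemble period at coupling multiplier `q` equals `target_period`. With the
#' defaults (intrinsic 25.5 h, target 23.5 h, q = 10) this gives
#' K = 0.0020970 1/h.
#'
#' @param lambda Radial relaxation rate (1/h).
#' @param twist Twist parameter (1/h); must be non-zero.
#' @param period Mean intrinsic period (h).
#' @param target_period Desired synchronized ensemble period (h) at `q`.
#' @param q Coupling multiplier at which the target is met.
#' @return Coupling constant K in 1/h. Only the twist magnitude enters: the
#'   returned K sets the size of the mean-field frequency shift, whose sign
#'   follows the sign of the twist (negative twist shortens the period,
#'   positive twist lengthens it by the symmetric amount).
#' @export
calibrate_coupling <- function(lambda = 0.02, twist = -0.01,
                               period = 25.5, target_period = 23.5, q = 10) {
  stopifnot(q > 0)
  if (twist == 0) {
    stop("zero twist produces no frequency shift; supply K directly instead of calibrating")
  }
  omega <- 2 * pi / period
  omega_t <- 2 * pi / target_period
  abs((omega_t - omega) * lambda / (twist * 2 * q))
}

#' Draw heterogeneous intrinsic periods
#'
#' Periods are sampled from a normal distribution (default mean 25.5 h,
#' SD 1 h) truncated at `truncate` standard deviations to avoid pathological
#' draws.
#'
#' @param n Number of oscillators.
#' @param mean,sd Mean and SD of the period distribution (h).
#' @param truncate Truncation half-width in SD units.
#' @param seed Optional integer seed.
#' @return Numeric vector of periods (h).
#' @export
draw_periods <- function(n, mean = 25.5, sd = 1, truncate = 4, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  tau <- stats::rnorm(n, mean, sd)
  bad <- abs(tau - mean) > truncate * sd
  while (any(bad)) {
    tau[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(tau - mean) > truncate * sd
  }
  tau
}

osc_param_table <- function(n, amplitude, lambda, twist, period) {
  tibble::tibble(
    oscillator = seq_len(n),
    amplitude = rep_len(amplitude, n),
    lambda = rep_len(lambda, n),
    twist = rep_len(twist, n),
    period_h = rep_len(period, n),
    omega = 2 * pi / rep_len(period, n)
  )
}

#' Build a 1D chain of nearest-neighbour coupled twist oscillators
#'
#' Each oscillator receives additive Cartesian coupling `q*K*(x[i-1] + x[i+1])`
#' (and likewise in y) from its immediate neighbours only, with open
#' boundaries: the end cells have a single neighbour, so the summed input
#' strength is `2*q*K` for interior cells and `q*K` at the boundary. This
#' boundary asymmetry is what lets the tissue centre accumulate more coupling,
#' expand in amplitude, and (under negative twist) phase-lead.
#'
#' @param n Number of oscillators (>= 2).
#' @param K Coupling constant (1/h, >= 0). Default: [calibrate_coupling()]
#'   with the supplied `lambda`, `twist` and mean of `period`.
#' @param q Integer coupling multiplier >= 0 (0 = uncoupled control).
#' @param amplitude,lambda,twist Single-cell parameters, recycled to length `n`.
#' @param period Intrinsic period(s) in hours, recycled to length `n`.
#' @return A `network_spec`.
#' @examples
#' spec <- chain_network(3, K = 1, q = 1, period = 24)
#' mean_field(spec)$k_in   # 1, 2, 1
#' @export
chain_network <- function(n = 60, K = NULL, q = 1, amplitude = 1,
                          lambda = 0.02, twist = -0.01, period = 25.5) {
  if (n < 2) stop("a chain needs at least 2 oscillators")
  stopifnot(q >= 0, q == round(q))
  if (is.null(K)) {
    K <- calibrate_coupling(lambda = lambda[1], twist = twist[1],
                            period = mean(period))
  }
  stopifnot(K >= 0)
  W <- matrix(0, n, n)
  idx <- seq_len(n - 1)
  W[cbind(idx, idx + 1)] <- K
  W[cbind(idx + 1, idx)] <- K
  new_network_spec(
    n = n, topology = "chain", coupling = W, q = as.integer(q),
    params = osc_param_table(n, amplitude, lambda, twist, period),
    geometry = tibble::tibble(oscillator = seq_len(n), row = 1L, col = seq_len(n))
  )
}

# lattice neighbour pairs for a set of retained cells
lattice_edges <- function(cells, scheme, radius) {
  offs <- if (scheme == "von_neumann") {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  } else {
    r <- floor(radius)
    g <- expand.grid(dr = -r:r, dc = -r:r)
    g <- g[sqrt(g$dr^2 + g$dc^2) <= radius & !(g$dr == 0 & g$dc == 0), ]
    g
  }
  key <- paste(cells$row, cells$col)
  id <- stats::setNames(cells$oscillator, key)
  out <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- paste(cells$row + offs$dr[k], cells$col + offs$dc[k])
    hit <- nb %in% key
    if (any(hit)) {
      out[[length(out) + 1]] <- cbind(cells$oscillator[hit], unname(id[nb[hit]]))
    }
  }
  do.call(rbind, out)
}

#' Build a 2D grid of coupled twist oscillators
#'
#' Cells couple through a von Neumann neighbourhood (the four most adjacent
#' cells) or to all neighbours within a Euclidean `radius` on the lattice.
#' The additive Cartesian coupling term is `0.5 * sum_j K_ij * x_j` (and in
#' y), i.e. the 0.5 prefactor of the 2D formulation is baked into the coupling
#' matrix. An optional boolean `mask` restricts the grid to a tissue-like
#' geometry; masked-out cells carry no couplings.
#'
#' @param nrow,ncol Grid dimensions (ignored if `mask` is given).
#' @param mask Optional logical matrix; `TRUE` cells are retained.
#' @param scheme `"von_neumann"` (default) or `"radius"`.
#' @param radius Neighbourhood radius for `scheme = "radius"` (e.g. 1.5 gives
#'   the 8-cell Moore neighbourhood).
#' @param K Coupling constant (1/h); default as in [chain_network()].
#' @param q Integer coupling multiplier >= 0.
#' @inheritParams chain_network
#' @return A `network_spec`.
#' @export
grid_network <- function(nrow = 8, ncol = 8, mask = NULL,
                         scheme = c("von_neumann", "radius"), radius = 1.5,
                         K = NULL, q = 1, amplitude = 1, lambda = 0.02,
                         twist = -0.01, period = 25.5) {
  scheme <- match.arg(scheme)
  stopifnot(q >= 0, q == round(q))
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), is.matrix(mask))
    if (!any(mask)) stop("empty mask: no cells retained")
    nrow <- base::nrow(mask); ncol <- base::ncol(mask)
    keep <- which(mask, arr.ind = TRUE)
  } else {
    keep <- as.matrix(expand.grid(row = seq_len(nrow), col = seq_len(ncol)))
  }
  n <- base::nrow(keep)
  cells <- tibble::tibble(oscillator = seq_len(n),
                          row = as.integer(keep[, 1]), col = as.integer(keep[, 2]))
  if (is.null(K)) {
    K <- calibrate_coupling(lambda = lambda[1], twist = twist[1],
                            period = mean(period))
  }
  stopifnot(K >= 0)
  W <- matrix(0, n, n)
  e <- lattice_edges(cells, scheme, radius)
  if (!is.null(e)) W[e] <- 0.5 * K
  deg <- rowSums(W > 0)
  if (any(deg == 0) && n > 1) {
    warning(sum(deg == 0), " cell(s) have no neighbours (disconnected mask)")
  }
  new_network_spec(
    n = n, topology = if (scheme == "von_neumann") "grid_von_neumann" else "grid_radius",
    coupling = W, q = as.integer(q),
    params = osc_param_table(n, amplitude, lambda, twist, period),
    geometry = cells
  )
}

#' Mean-field prediction of stationary radius and shifted frequency
#'
#' Near synchrony, each oscillator's radial equation closes to
#' `dr/dt = lambda*r*(A - r) + K_i*r` with `K_i = q * sum_j K_ij` the summed
#' coupling input, giving the stationary radius `r* = K_i/lambda + A` and the
#' shifted angular velocity `omega' = omega - twist*K_i/lambda`. Under
#' negative twist the coupled ensemble therefore runs faster than its mean
#' intrinsic period. The approximation assumes near-synchrony and is least
#' accurate at network boundaries.
#'
#' @param spec A `network_spec`.
#' @return A tibble with columns `oscillator`, `k_in` (1/h), `r_star`,
#'   `omega_prime` (rad/h) and `period_h` (2*pi/omega').
#' @export
mean_field <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  k_in <- spec$q * rowSums(spec$coupling)
  p <- spec$params
  omega_prime <- p$omega - p$twist * k_in / p$lambda
  tibble::tibble(
    oscillator = p$oscillator,
    k_in = k_in,
    r_star = k_in / p$lambda + p$amplitude,
    omega_prime = omega_prime,
    period_h = 2 * pi / omega_prime
  )
}

#' Integrate a coupled oscillator network
#'
#' Integrates the Cartesian form of the coupled twist-oscillator equations
#' with `deSolve::ode` (lsoda). Initial radii default to the single-cell
#' amplitude; initial phases are drawn as `2*pi*N(0, phase_sd_h)/period_i`
#' (an SD of `phase_sd_h` hours converted to radians per oscillator), or can
#' be supplied explicitly through `init`.
#'
#' @param spec A `network_spec`.
#' @param t_end End time (h); alternatively give `days`.
#' @param days Simulation length in days (used when `t_end` is NULL).
#' @param dt Output sampling interval (h).
#' @param phase_sd_h SD of the initial phase distribution, in hours.
#' @param init Optional tibble/data frame with columns `x`, `y` (one row per
#'   oscillator) overriding the random initial conditions.
#' @param seed Optional integer seed for the initial phase draw.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble of class `twist_trajectory` with columns `time_h`,
#'   `oscillator`, `x`, `y`, `r`, `phase_rad` (per-oscillator unwrapped).
#'   The generating `spec` and `dt` are attached as attributes.
#' @export
simulate_network <- function(spec, t_end = NULL, days = 12, dt = 0.25,
                             phase_sd_h = 1, init = NULL, seed = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "network_spec"), dt > 0)
  if (is.null(t_end)) t_end <- days * 24
  stopifnot(is.finite(t_end), t_end > 0)
  n <- spec$n
  p <- spec$params
  if (is.null(init)) {
    if (!is.null(seed)) withr::local_seed(seed)
    phi0 <- 2 * pi * stats::rnorm(n, 0, phase_sd_h) / p$period_h
    x0 <- p$amplitude * cos(phi0)
    y0 <- p$amplitude * sin(phi0)
  } else {
    stopifnot(nrow(init) == n, all(c("x", "y") %in% names(init)))
    x0 <- init$x; y0 <- init$y
  }
  stopifnot(all(is.finite(x0)), all(is.finite(y0)))
  C <- spec$q * spec$coupling
  coupled <- any(C != 0)
  A <- p$amplitude; lam <- p$lambda; eps <- p$twist; om <- p$omega
  deriv <- function(t, state, parms) {
    x <- state[1:n]; y <- state[(n + 1):(2 * n)]
    r <- sqrt(x^2 + y^2)
    gap <- A - r
    dx <- gap * (lam * x - eps * y) - om * y
    dy <- gap * (lam * y + eps * x) + om * x
    if (coupled) {
      dx <- dx + as.vector(C %*% x)
      dy <- dy + as.vector(C %*% y)
    }
    list(c(dx, dy))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = c(x0, y0), times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("network integration failed (lsoda istate = ", attr(sol, "istate")[1],
         "); try smaller dt or looser tolerances")
  }
  xs <- sol[, 1 + (1:n), drop = FALSE]
  ys <- sol[, 1 + n + (1:n), drop = FALSE]
  phase <- atan2(ys, xs)
  phase <- apply(phase, 2, unwrap_phase)
  out <- tibble::tibble(
    time_h = rep(times, times = n),
    oscillator = rep(seq_len(n), each = length(times)),
    x = as.vector(xs), y = as.vector(ys),
    r = as.vector(sqrt(xs^2 + ys^2)),
    phase_rad = as.vector(phase)
  )
  class(out) <- c("twist_trajectory", class(out))
  attr(out, "spec") <- spec
  attr(out, "dt") <- dt
  out
}

#' Collapse a trajectory to one ensemble signal
#'
#' Population proxy for a photomultiplier recording: the mean (default) or sum
#' of one Cartesian component across oscillators at each time point, with an
#' optional linear rescale to kcpm-like units.
#'
#' @param traj A `twist_trajectory`.
#' @param mode `"mean"` or `"sum"`.
#' @param component Column to aggregate (default `"x"`).
#' @param scale Multiplicative rescale applied to the aggregated signal.
#' @return A tibble with columns `time_h`, `signal`.
#' @export
ensemble_signal <- function(traj, mode = c("mean", "sum"), component = "x",
                            scale = 1) {
  mode <- match.arg(mode)
  stopifnot(nrow(traj) > 0, component %in% names(traj))
  agg <- if (mode == "mean") mean else sum
  traj |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(signal = agg(.data[[component]]), .groups = "drop") |>
    dplyr::mutate(signal = .data$signal * scale)
}

# ensemble period + RMS amplitude + order parameter for one run
summarise_run <- function(traj, discard_h = 48, days = 10, band = c(16, 32)) {
  sig <- ensemble_signal(traj)
  sig <- sig[sig$time_h >= discard_h, ]
  est <- estimate_period(sig, band = band)
  rms <- rms_amplitude(sig, days = min(days, floor((max(sig$time_h) - min(sig$time_h)) / 24)))
  op <- traj |>
    dplyr::filter(.data$time_h >= discard_h) |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(R = Mod(mean(exp(1i * .data$phase_rad))), .groups = "drop")
  tibble::tibble(period_h = est$period_h, rhythmic = est$rhythmic,
                 rms_amplitude = rms, order_parameter = mean(op$R))
}

#' Dose-response sweep over the coupling multiplier
#'
#' Emulates graded gap-junction inhibition: for each coupling multiplier `q`
#' (0 = fully blocked, 10 = full coupling by default) and each replicate, the
#' same seeded draw of intrinsic periods and initial phases is integrated and
#' the ensemble period (interpolated FFT), RMS amplitude (after transient
#' discard) and Kuramoto order parameter are tabulated. Runs whose
#' time-averaged order parameter falls below `sync_threshold` are flagged as
#' unsynchronized rather than silently averaged; their ensemble period should
#' be interpreted with care.
#'
#' @param q Integer vector of coupling multipliers.
#' @param n Chain length.
#' @param n_replicates Number of replicate parameter draws.
#' @param seeds Integer vector of replicate seeds (distinct); default
#'   `seq_len(n_replicates)`.
#' @param days Simulated days per run.
#' @param discard_h Transient discarded before period/amplitude estimation (h).
#' @param K Coupling constant; default [calibrate_coupling()].
#' @param period_mean,period_sd Intrinsic period distribution (h).
#' @param phase_sd_h Initial phase SD (h).
#' @param sync_threshold Minimum time-averaged order parameter to report a
#'   synchronized ensemble period.
#' @inheritParams chain_network
#' @return A tibble of class `dose_sweep`: columns `q`, `replicate`, `seed`,
#'   `period_h`, `rms_amplitude`, `order_parameter`, `synchronized`.
#' @export
dose_response_sweep <- function(q = 0:10, n = 60, n_replicates = 5,
                                seeds = seq_len(n_replicates), days = 12,
                                discard_h = 48, K = NULL, amplitude = 1,
                                lambda = 0.02, twist = -0.01,
                                period_mean = 25.5, period_sd = 1,
                                phase_sd_h = 1, sync_threshold = 0.6) {
  stopifnot(all(q >= 0), all(q == round(q)), length(seeds) == n_replicates,
            !anyDuplicated(seeds))
  if (is.null(K)) K <- calibrate_coupling(lambda = lambda, twist = twist,
                                          period = period_mean)
  res <- purrr::map2(seq_along(seeds), seeds, function(rep_i, s) {
    tau <- draw_periods(n, period_mean, period_sd, seed = s)
    withr::with_seed(s + 10000L, {
      phi0 <- 2 * pi * stats::rnorm(n, 0, phase_sd_h) / tau
    })
    init <- tibble::tibble(x = amplitude * cos(phi0), y = amplitude * sin(phi0))
    purrr::map(q, function(qi) {
      spec <- chain_network(n, K = K, q = qi, amplitude = amplitude,
                            lambda = lambda, twist = twist, period = tau)
      traj <- simulate_network(spec, days = days, init = init)
      dplyr::bind_cols(
        tibble::tibble(q = qi, replicate = rep_i, seed = s),
        summarise_run(traj, discard_h = discard_h)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  res$synchronized <- res$order_parameter >= sync_threshold
  res <- res[, c("q", "replicate", "seed", "period_h", "rms_amplitude",
                 "order_parameter", "synchronized")]
  class(res) <- c("dose_sweep", class(res))
  res
}
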