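# Circular-variable spatial autocorrelation: signed angular distance,
# circular mean, the angular and complex-embedding variants of Moran's I with
# binary nearest-neighbour weights, a Monte-Carlo permutation null, and the
# extraction of peak-phase maps from simulated trajectories.

#' Signed circular distance between two angles
#'
#' `atan2(sin(x - y), cos(x - y))`: the signed angular difference wrapped to
#' `(-pi, pi]`. Antisymmetric: `circular_distance(a, b) == -circular_distance(b, a)`.
#'
#' @param x,y Angles in radians (vectorised, recycled).
#' @return Signed angle(s) in `(-pi, pi]`.
#' @export
circular_distance <- function(x, y) atan2(sin(x - y), cos(x - y))

#' Circular mean direction and resultant length
#'
#' Quadrant-correct mean direction `atan2(mean(sin), mean(cos))` of a set of
#' circular values, with its resultant length. When the resultant vanishes
#' (e.g. exactly antipodal phases) the mean direction is undefined and
#' flagged.
#'
#' @param phases Angles in radians.
#' @param tol Resultant length below which the mean is declared undefined.
#' @return One-row tibble: `mean_rad`, `resultant`, `degenerate`.
#' @export
circular_mean <- function(phases, tol = 1e-10) {
  stopifnot(length(phases) >= 1)
  C <- mean(cos(phases)); S <- mean(sin(phases))
  R <- sqrt(C^2 + S^2)
  deg <- R < tol
  tibble::tibble(mean_rad = if (deg) NA_real_ else atan2(S, C),
                 resultant = R, degenerate = deg)
}

#' Build a phase map with nearest-neighbour weights
#'
#' A phase map holds wrapped circular phases on a 1D chain or a 2D grid (or
#' masked grid) together with a binary symmetric nearest-neighbour weight
#' structure: chain neighbours are `|i - j| = 1`; grid neighbours are the von
#' Neumann 4-neighbourhood. Units with no retained neighbour are dropped with
#' a warning.
#'
#' @param data Tibble with a phase column and either an index column (`col`)
#'   for a chain or both `row` and `col` for a grid.
#' @param phase,row,col Column names (unquoted). Leave `row` at its default
#'   for chains without a `row` column.
#' @return Object of class `phase_map`: tibble `id`, `row`, `col`,
#'   `phase_rad` with an `edges` attribute (two-column matrix of directed
#'   neighbour pairs; both directions present).
#' @export
as_phase_map <- function(data, phase = phase_rad, row = row, col = col) {
  ph <- dplyr::pull(data, {{ phase }})
  cl <- dplyr::pull(data, {{ col }})
  rw <- tryCatch(dplyr::pull(data, {{ row }}), error = function(e) rep(1L, length(cl)))
  stopifnot(all(is.finite(ph)))
  m <- tibble::tibble(id = seq_along(ph), row = as.integer(rw),
                      col = as.integer(cl), phase_rad = ph %% (2 * pi))
  e <- lattice_edges(
    tibble::tibble(oscillator = m$id, row = m$row, col = m$col),
    scheme = "von_neumann", radius = 1
  )
  if (is.null(e)) stop("no neighbour pairs: the map has no adjacent units")
  iso <- setdiff(m$id, unique(as.vector(e)))
  if (length(iso) > 0) {
    warning(length(iso), " unit(s) without neighbours dropped from the phase map")
    m <- m[!m$id %in% iso, ]
    m$id <- seq_len(nrow(m))
    e <- lattice_edges(tibble::tibble(oscillator = m$id, row = m$row, col = m$col),
                       scheme = "von_neumann", radius = 1)
  }
  if (nrow(m) < 3) stop("need at least 3 connected units")
  class(m) <- c("phase_map", class(m))
  attr(m, "edges") <- e
  m
}

#' @export
print.phase_map <- function(x, ...) {
  cat("<phase_map>", nrow(x), "units,", nrow(attr(x, "edges")) / 2,
      "neighbour pairs\n")
  NextMethod()
}

# core statistics on deviation vectors; edges is the directed pair matrix
moran_stat_angular <- function(z, edges) {
  num <- sum(z[edges[, 1]] * z[edges[, 2]])
  den <- sum(z^2)
  (length(z) / nrow(edges)) * num / den
}

moran_stat_circular <- function(u, ubar, edges) {
  z <- u - ubar
  num <- sum(Conj(z[edges[, 1]]) * z[edges[, 2]])
  den <- sum(Mod(z)^2)
  (length(u) / nrow(edges)) * num / den
}

#' Moran's I for circular phase data
#'
#' Spatial autocorrelation of wrapped phases under binary nearest-neighbour
#' weights, in two variants. The `"angular"` variant applies the standard
#' Moran's I to signed circular deviations from the circular mean,
#' `d_theta(X_i, Xbar)`; the `"circular"` variant embeds phases on the unit
#' circle, `u_i = exp(1i * theta_i)`, and computes the analogous complex
#' statistic (its real part is reported; the imaginary part is attached).
#' Significance comes from a Monte-Carlo permutation null (random relabelling
#' of phases across positions): `p = (1 + #(null >= observed)) / (n_perm + 1)`
#' one-sided for positive autocorrelation by default. Under the null both
#' variants have expectation `-1/(N-1)`.
#'
#' Fully synchronized maps (all phases identical, or unit resultant) make
#' both formulas 0/0; these return a degenerate flag and no statistic.
#'
#' @param map A `phase_map` from [as_phase_map()] or [peak_phase_map()].
#' @param variant `"angular"` (default) or `"circular"`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional seed for the permutation draw.
#' @param alternative `"greater"` (positive autocorrelation), `"less"`, or
#'   `"two.sided"`.
#' @return One-row tibble of class `moran_result`: `statistic`, `variant`,
#'   `p_value`, `n_perm`, `null_mean`, `null_sd`, `n`, `degenerate`. For the
#'   circular variant the imaginary part is in attribute `"imaginary"`.
#' @export
morans_i <- function(map, variant = c("angular", "circular"), n_perm = 999,
                     seed = NULL, alternative = c("greater", "less", "two.sided")) {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  stopifnot(inherits(map, "phase_map"))
  if (n_perm < 1) stop("n_perm must be at least 1")
  edges <- attr(map, "edges")
  ph <- map$phase_rad
  n <- length(ph)
  cm <- circular_mean(ph)
  degen_row <- function() {
    out <- tibble::tibble(statistic = NA_real_, variant = variant,
                          p_value = NA_real_, n_perm = n_perm,
                          null_mean = NA_real_, null_sd = NA_real_,
                          n = n, degenerate = TRUE)
    class(out) <- c("moran_result", class(out))
    out
  }
  if (variant == "angular") {
    if (cm$degenerate) stop("circular mean undefined (zero resultant); cannot form deviations")
    z <- circular_distance(ph, cm$mean_rad)
    if (all(abs(z) < 1e-12)) return(degen_row())  # complete synchrony: 0/0
    obs <- moran_stat_angular(z, edges)
    statfun <- function(perm) moran_stat_angular(z[perm], edges)
    imag <- NULL
  } else {
    u <- exp(1i * ph)
    ubar <- mean(u)
    if (1 - Mod(ubar)^2 < 1e-12) return(degen_row())  # unit resultant: 0/0
    obs_c <- moran_stat_circular(u, ubar, edges)
    obs <- Re(obs_c); imag <- Im(obs_c)
    statfun <- function(perm) Re(moran_stat_circular(u[perm], ubar, edges))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  null <- vapply(seq_len(n_perm), function(i) statfun(sample.int(n)), numeric(1))
  p <- switch(alternative,
    greater = (1 + sum(null >= obs)) / (n_perm + 1),
    less = (1 + sum(null <= obs)) / (n_perm + 1),
    two.sided = {
      dev <- abs(null - mean(null))
      (1 + sum(dev >= abs(obs - mean(null)))) / (n_perm + 1)
    })
  out <- tibble::tibble(statistic = obs, variant = variant, p_value = p,
                        n_perm = n_perm, null_mean = mean(null),
                        null_sd = stats::sd(null), n = n, degenerate = FALSE)
  class(out) <- c("moran_result", class(out))
  if (!is.null(imag)) attr(out, "imaginary") <- imag
  out
}

#' Extract a per-unit peak-phase map from a trajectory
#'
#' For each oscillator, finds the peak of its (detrended) signal inside one
#' cycle window after the transient, refines the peak time by quadratic
#' interpolation, and converts it to a phase
#' `2*pi*(t_peak - window start)/period`, wrapped to `[0, 2*pi)`. Cycle
#' windows are `[discard_h + (cycle-1)*P, discard_h + cycle*P)` with `P` the
#' ensemble period (estimated from the ensemble-mean signal when not given).
#' Units whose maximum falls on a window edge (no interior peak) are flagged
#' and excluded; neighbour weights are rebuilt on the retained units.
#'
#' @param traj A `twist_trajectory`.
#' @param cycle Which post-transient cycle to use (1-based).
#' @param discard_h Transient discarded before the first cycle window (h).
#' @param period_h Ensemble period; estimated when NULL.
#' @param signal Trajectory column holding the oscillation (default `"x"`).
#' @return A `phase_map` (geometry taken from the trajectory's network spec).
#' @export
peak_phase_map <- function(traj, cycle = 2, discard_h = 48, period_h = NULL,
                           signal = "x") {
  stopifnot(inherits(traj, "twist_trajectory"), cycle >= 1)
  spec <- attr(traj, "spec")
  if (is.null(period_h)) {
    sig <- ensemble_signal(traj, component = signal)
    period_h <- estimate_period(sig[sig$time_h >= discard_h, ])$period_h
    if (is.na(period_h)) stop("ensemble signal is arrhythmic; supply period_h")
  }
  t0 <- discard_h + (cycle - 1) * period_h
  t1 <- t0 + period_h
  if (t1 > max(traj$time_h)) stop("cycle window extends past the trajectory end")
  win <- traj[traj$time_h >= t0 & traj$time_h <= t1, ]
  peaks <- win |>
    dplyr::group_by(.data$oscillator) |>
    dplyr::group_modify(function(d, key) {
      s <- d[[signal]]; tt <- d$time_h
      k <- which.max(s)
      if (k == 1 || k == length(s)) {
        return(tibble::tibble(t_peak = NA_real_))
      }
      y <- s[(k - 1):(k + 1)]
      denom <- y[1] - 2 * y[2] + y[3]
      delta <- if (abs(denom) > 0) 0.5 * (y[1] - y[3]) / denom else 0
      tibble::tibble(t_peak = tt[k] + delta * stats::median(diff(tt)))
    }) |>
    dplyr::ungroup()
  bad <- is.na(peaks$t_peak)
  if (all(bad)) stop("no unit has an interior peak in the chosen cycle")
  if (any(bad)) {
    warning(sum(bad), " unit(s) without an interior peak excluded from the phase map")
  }
  geom <- spec$geometry
  keep <- peaks$oscillator[!bad]
  df <- tibble::tibble(
    row = geom$row[match(keep, geom$oscillator)],
    col = geom$col[match(keep, geom$oscillator)],
    phase_rad = (2 * pi * (peaks$t_peak[!bad] - t0) / period_h) %% (2 * pi)
  )
  as_phase_map(df)
}
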