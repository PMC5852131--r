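# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the developmental exponential fit
#'
#' @param x A `dev_fit` from [fit_development()].
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.dev_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.dev_fit
#' @return For `glance`: one-row tibble `sigma`, `df.residual`, `nobs`,
#'   `degenerate`, `converged`.
#' @export
glance.dev_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(sigma = s$sigma, df.residual = stats::df.residual(x$fit),
                 nobs = x$n, degenerate = x$degenerate,
                 converged = x$fit$convInfo$isConv %||% TRUE)
}

#' Tidy a chi-squared periodogram
#'
#' @param x A `chisq_periodogram`.
#' @param ... Unused.
#' @return For `tidy`: the per-period statistic curve. For `glance`: a
#'   one-row summary with the best period and its significance.
#' @export
tidy.chisq_periodogram <- function(x, ...) x$curve

#' @rdname tidy.chisq_periodogram
#' @export
glance.chisq_periodogram <- function(x, ...) {
  tibble::tibble(best_period_h = x$best_period_h, significant = x$significant,
                 alpha = x$alpha, adjust = x$adjust, n_periods = x$n_periods)
}

#' Plot a simulated trajectory
#'
#' One line per oscillator (the x component), with the ensemble mean overlaid.
#'
#' @param object A `twist_trajectory`.
#' @param max_units Plot at most this many individual oscillators.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twist_trajectory <- function(object, max_units = 20, ...) {
  units <- unique(object$oscillator)
  shown <- units[seq(1, length(units), length.out = min(max_units, length(units)))]
  ens <- ensemble_signal(object)
  ggplot2::ggplot(object[object$oscillator %in% shown, ],
                  ggplot2::aes(x = .data$time_h, y = .data$x,
                               group = .data$oscillator)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_line(data = ens, ggplot2::aes(y = .data$signal, group = NULL),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = "x (ensemble mean in red)")
}

#' Plot a chi-squared periodogram
#'
#' @param object A `chisq_periodogram`.
#' @param ... Unused.
#' @return A ggplot object: Q statistic per candidate period with the
#'   significance line.
#' @export
autoplot.chisq_periodogram <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$period_h)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$qp)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$line), linetype = 2) +
    ggplot2::labs(x = "period (h)", y = "Q statistic (dashed: significance line)")
}

#' Plot a dose-response sweep
#'
#' Ensemble period and RMS amplitude against the coupling multiplier q, one
#' point per replicate with replicate means joined.
#'
#' @param object A `dose_sweep` from [dose_response_sweep()].
#' @param ... Unused.
#' @return A ggplot object (two facets: period, amplitude).
#' @export
autoplot.dose_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("q", "replicate", "period_h", "rms_amplitude")],
    cols = c("period_h", "rms_amplitude"),
    names_to = "metric", values_to = "value"
  )
  means <- long |>
    dplyr::group_by(.data$q, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$q, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = means, colour = "firebrick") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "coupling multiplier q", y = NULL)
}

#' Plot a phase map
#'
#' Tile map of wrapped phases on the chain or grid.
#'
#' @param object A `phase_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$phase_rad)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = c("#2166ac", "#f7f7f7", "#b2182b",
                                              "#2166ac"),
                                  limits = c(0, 2 * pi)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "phase (rad)")
}
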