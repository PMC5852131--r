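# Rhythm metrics for bioluminescence-style time series: running-mean
# detrending, interpolated-FFT period estimation, RMS amplitude over a fixed
# window, the Sokolove-Bushell chi-squared periodogram, the exponential
# developmental fit, bootstrap period-amplitude correlation, and synchrony
# metrics for multi-oscillator phase series.

#' Remove a slow baseline with a centred running mean
#'
#' Subtracts a centred moving average of width `window_h` (partial windows at
#' the record edges), removing photomultiplier baseline drift while leaving
#' circadian-band oscillations nearly untouched.
#'
#' @param data Tibble with a time column and a signal column.
#' @param window_h Running-mean window in hours; must be shorter than the record.
#' @param time,signal Column names (unquoted) of time (h) and signal.
#' @return The input tibble with `signal` replaced by the detrended signal and
#'   an added `baseline` column.
#' @export
detrend_signal <- function(data, window_h = 24, time = time_h, signal = signal) {
  tcol <- rlang::enquo(time); scol <- rlang::enquo(signal)
  t <- dplyr::pull(data, !!tcol); s <- dplyr::pull(data, !!scol)
  n <- length(s)
  stopifnot(n > 2)
  dt <- stats::median(diff(t))
  half <- floor((window_h / dt) / 2)
  if (2 * half + 1 >= n) stop("detrending window must be shorter than the record")
  cs <- cumsum(c(0, s))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  baseline <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  out <- data
  out[[rlang::as_name(scol)]] <- s - baseline
  out$baseline <- baseline
  out
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Estimate the dominant circadian period by interpolated FFT
#'
#' Detrends (optionally), applies a Hann window, zero-pads to `pad_factor`
#' times the record length, and locates the largest spectral peak inside
#' `band` (h), refining the peak frequency by local quadratic interpolation of
#' the log-magnitude. A record is flagged arrhythmic when the in-band peak
#' power does not exceed `snr_min` times the median out-of-band power.
#'
#' @inheritParams detrend_signal
#' @param band Period search band in hours, default 16-32 h.
#' @param detrend Apply [detrend_signal()] first (default TRUE).
#' @param pad_factor Zero-padding factor for the FFT.
#' @param snr_min Peak-to-median-noise power ratio below which the record is
#'   declared arrhythmic.
#' @return One-row tibble: `period_h` (NA when arrhythmic), `power`, `snr`,
#'   `rhythmic`.
#' @export
estimate_period <- function(data, band = c(16, 32), time = time_h,
                            signal = signal, detrend = TRUE, pad_factor = 8,
                            snr_min = 5) {
  tcol <- rlang::enquo(time); scol <- rlang::enquo(signal)
  t <- dplyr::pull(data, !!tcol); s <- dplyr::pull(data, !!scol)
  dt <- stats::median(diff(t))
  if ((max(t) - min(t)) < 5 * band[1]) {
    stop("record too short: need at least ~5 cycles of the shortest band period")
  }
  if (detrend) {
    dd <- detrend_signal(data, time = {{ time }}, signal = {{ signal }})
    s <- dplyr::pull(dd, {{ signal }})
  }
  n <- length(s)
  sw <- (s - mean(s)) * hann(n)
  nfft <- pad_factor * n
  spec <- Mod(stats::fft(c(sw, rep(0, nfft - n))))^2
  freq <- (seq_len(nfft) - 1) / (nfft * dt)
  half <- 2:(floor(nfft / 2))
  spec <- spec[half]; freq <- freq[half]
  per <- 1 / freq
  inband <- per >= band[1] & per <= band[2]
  if (!any(inband)) stop("no spectral bins fall inside the requested band")
  # noise floor: out-of-band power away from the near-DC leakage
  noise <- per < band[1] | (per > band[2] & per < 4 * band[2])
  noise_med <- stats::median(spec[noise])
  k <- which(inband)[which.max(spec[inband])]
  snr <- spec[k] / max(noise_med, .Machine$double.eps)
  rhythmic <- snr >= snr_min
  period <- NA_real_
  if (rhythmic) {
    # quadratic interpolation on log power around the peak bin
    if (k > 1 && k < length(spec)) {
      y <- log(spec[(k - 1):(k + 1)] + .Machine$double.xmin)
      denom <- y[1] - 2 * y[2] + y[3]
      delta <- if (abs(denom) > 0) 0.5 * (y[1] - y[3]) / denom else 0
      delta <- max(min(delta, 0.5), -0.5)
    } else delta <- 0
    fpk <- freq[k] + delta / (nfft * dt)
    period <- 1 / fpk
  }
  tibble::tibble(period_h = period, power = spec[k], snr = snr,
                 rhythmic = rhythmic)
}

#' RMS amplitude over a fixed window
#'
#' Root-mean-square of the (by default detrended) signal over the first
#' `days` days of the record, the standard equal-duration amplitude measure
#' for bioluminescence recordings.
#'
#' @inheritParams detrend_signal
#' @param days Window length in days; the record must cover it.
#' @param detrend Detrend before the RMS (default TRUE); set FALSE for the
#'   raw-oscillation convention.
#' @return RMS amplitude (same units as the signal).
#' @export
rms_amplitude <- function(data, days = 10, time = time_h, signal = signal,
                          detrend = TRUE, window_h = 24) {
  tcol <- rlang::enquo(time); scol <- rlang::enquo(signal)
  t <- dplyr::pull(data, !!tcol)
  # a sample covers dt of time: a record of n samples spans n*dt
  if ((max(t) - min(t)) + stats::median(diff(t)) < days * 24 - 1e-9) {
    stop("record covers ", round((max(t) - min(t)) / 24, 2),
         " days but ", days, " were requested; refusing to truncate silently")
  }
  if (detrend) data <- detrend_signal(data, window_h = window_h,
                                      time = {{ time }}, signal = {{ signal }})
  s <- dplyr::pull(data, {{ signal }})
  keep <- t - min(t) <= days * 24
  sqrt(mean(s[keep]^2))
}

#' Sokolove-Bushell chi-squared periodogram
#'
#' Folds a binned event/count series at each candidate period and computes
#' `Q_P = N * sum_h n_h * (M_h - M)^2 / sum_i (x_i - M)^2`, distributed
#' approximately as chi-squared with (bins-1) degrees of freedom under the
#' null of no periodicity. The best period is the one with the smallest
#' per-period p-value; scan-level significance uses a Bonferroni correction
#' over the tested periods by default.
#'
#' @param events Tibble with columns `bin_start_h` and `count` on a uniform
#'   bin grid.
#' @param periods Candidate periods (h), default `seq(20, 28, by = 0.1)`.
#' @param alpha Significance level.
#' @param adjust `"bonferroni"` (scan-level) or `"none"` (per-period).
#' @return Object of class `chisq_periodogram`: list with `curve` (tibble of
#'   `period_h`, `qp`, `df`, `p_value`, `line`), `best_period_h`,
#'   `significant`, `alpha`, `adjust`, `n_periods`.
#' @export
chisq_periodogram <- function(events, periods = seq(20, 28, by = 0.1),
                              alpha = 0.05, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("bin_start_h", "count") %in% names(events)),
            all(events$count >= 0))
  x <- events$count
  bw <- stats::median(diff(events$bin_start_h))
  n <- length(x)
  if (n * bw < 7 * 24 - 1e-6) stop("need at least 7 days of binned data")
  if (stats::var(x) == 0) {
    res <- list(curve = tibble::tibble(period_h = periods, qp = NA_real_,
                                       df = NA_integer_, p_value = NA_real_,
                                       line = NA_real_),
                best_period_h = NA_real_, significant = FALSE,
                alpha = alpha, adjust = adjust, n_periods = length(periods))
    class(res) <- "chisq_periodogram"
    return(res)
  }
  xbar <- mean(x)
  ssx <- sum((x - xbar)^2)
  m <- length(periods)
  crit_mult <- if (adjust == "bonferroni") m else 1
  rows <- lapply(periods, function(P) {
    pb <- round(P / bw)
    h <- (seq_len(n) - 1L) %% pb
    nh <- tabulate(h + 1L, nbins = pb)
    mh <- as.vector(rowsum(x, h)) / nh
    qp <- n * sum(nh * (mh - xbar)^2) / ssx
    df <- pb - 1L
    c(qp = qp, df = df,
      p = stats::pchisq(qp, df, lower.tail = FALSE),
      line = stats::qchisq(1 - alpha / crit_mult, df))
  })
  rows <- do.call(rbind, rows)
  curve <- tibble::tibble(period_h = periods, qp = rows[, "qp"],
                          df = as.integer(rows[, "df"]),
                          p_value = rows[, "p"], line = rows[, "line"])
  best <- which.min(curve$p_value)
  significant <- curve$p_value[best] * crit_mult <= alpha
  res <- list(curve = curve,
              best_period_h = if (significant) curve$period_h[best] else NA_real_,
              significant = significant, alpha = alpha, adjust = adjust,
              n_periods = m)
  class(res) <- "chisq_periodogram"
  res
}

#' @export
print.chisq_periodogram <- function(x, ...) {
  cat("<chisq_periodogram>", x$n_periods, "periods scanned;",
      if (x$significant) paste("best period", x$best_period_h, "h")
      else "no significant period", sprintf("(alpha = %g, %s)\n", x$alpha, x$adjust))
  invisible(x)
}

#' Exponential fit of the developmental period decline
#'
#' Least-squares fit of `period = a * exp(-age/tau_c) + c` to (age, period)
#' data, the three-parameter model for the postnatal shortening of the tissue
#' circadian period. Fitting uses Levenberg-Marquardt with several starting
#' values. A fit is flagged degenerate when the amplitude term is not
#' distinguishable from zero (no decline; `tau_c` unidentifiable).
#'
#' @param data Tibble of ages (days) and periods (h).
#' @param age,period Column names (unquoted).
#' @return Object of class `dev_fit`: list with `fit` (the `nls` object),
#'   `estimates` (named vector a, tau_c, c), `vcov`, `degenerate`, `n`.
#' @export
fit_development <- function(data, age = age_days, period = period_h) {
  acol <- rlang::enquo(age); pcol <- rlang::enquo(period)
  t <- dplyr::pull(data, !!acol); y <- dplyr::pull(data, !!pcol)
  if (length(unique(t)) < 4) stop("need at least 4 distinct ages")
  c0 <- mean(y[t >= stats::quantile(t, 0.75)])
  a0 <- mean(y[t <= stats::quantile(t, 0.25)]) - c0
  starts <- list(
    list(a = a0, tau_c = diff(range(t)) / 3, c = c0),
    list(a = if (a0 != 0) a0 else 1, tau_c = 10, c = mean(y)),
    list(a = 1, tau_c = 5, c = min(y))
  )
  fit <- NULL; tried <- character()
  for (st in starts) {
    f <- try(minpack.lm::nlsLM(y ~ a * exp(-t / tau_c) + c,
                               start = st, control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
    tried <- c(tried, paste(names(st), unlist(st), sep = "=", collapse = ", "))
    if (!inherits(f, "try-error")) { fit <- f; break }
  }
  if (is.null(fit)) {
    stop("exponential fit did not converge; starts tried: ",
         paste(tried, collapse = " | "))
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  degenerate <- is.na(se["a"]) || abs(est["a"]) < 2 * se["a"]
  res <- list(fit = fit, estimates = est, vcov = stats::vcov(fit),
              degenerate = degenerate, n = length(y))
  class(res) <- "dev_fit"
  res
}

#' @export
print.dev_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("<dev_fit> period = %.3f * exp(-age/%.3f) + %.3f h  (n = %d%s)\n",
              e["a"], e["tau_c"], e["c"], x$n,
              if (x$degenerate) ", degenerate: no resolvable decline" else ""))
  invisible(x)
}

#' Bootstrap period-amplitude correlation
#'
#' Pearson correlation between period and amplitude with a bootstrap mean and
#' SEM over `n_boot` resamples and a z-test p-value (z = bootstrap mean /
#' bootstrap SEM). With `size_control_n`, each resample draws that many pairs
#' without replacement, matching correlation strength across cohorts of
#' unequal size.
#'
#' @param data Tibble of (period, amplitude) pairs; at least 10 rows.
#' @param period,amplitude Column names (unquoted).
#' @param n_boot Number of resamples.
#' @param size_control_n Optional subsample size per resample.
#' @param seed Optional seed.
#' @return One-row tibble: `r`, `boot_mean`, `boot_sem`, `p_value`, `n`,
#'   `n_boot`, `size_control_n`.
#' @export
period_amplitude_correlation <- function(data, period = period_h,
                                         amplitude = rms_amplitude,
                                         n_boot = 10000, size_control_n = NULL,
                                         seed = NULL) {
  pcol <- rlang::enquo(period); acol <- rlang::enquo(amplitude)
  p <- dplyr::pull(data, !!pcol); a <- dplyr::pull(data, !!acol)
  n <- length(p)
  if (n < 10) stop("need at least 10 (period, amplitude) pairs")
  if (stats::var(p) == 0 || stats::var(a) == 0) {
    stop("zero variance in period or amplitude; correlation undefined")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  r <- stats::cor(p, a)
  draw <- if (is.null(size_control_n)) {
    function() sample.int(n, n, replace = TRUE)
  } else {
    stopifnot(size_control_n >= 3, size_control_n <= n)
    function() sample.int(n, size_control_n, replace = FALSE)
  }
  boots <- vapply(seq_len(n_boot), function(i) {
    idx <- draw()
    suppressWarnings(stats::cor(p[idx], a[idx]))
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  bm <- mean(boots); bs <- stats::sd(boots)
  pval <- 2 * stats::pnorm(-abs(bm / bs))
  tibble::tibble(r = r, boot_mean = bm, boot_sem = bs, p_value = pval,
                 n = n, n_boot = n_boot,
                 size_control_n = size_control_n %||% NA_integer_)
}

#' Synchrony metrics for a multi-oscillator phase series
#'
#' Computes the Kuramoto order parameter time course
#' `R(t) = |mean_i exp(i*phase_i(t))|` and the standard deviation of per-unit
#' FFT periods (from `x` when available, else `cos(phase_rad)`).
#'
#' @param data Tibble with columns `time_h`, `oscillator`, `phase_rad`
#'   (optionally `x`), e.g. a `twist_trajectory`.
#' @param discard_h Initial transient excluded (h).
#' @param band Period band for the per-unit FFT.
#' @return List with `order_parameter` (tibble `time_h`, `R`), `mean_R`,
#'   `period_sd_h`, and `periods` (per-unit tibble).
#' @export
sync_metrics <- function(data, discard_h = 0, band = c(16, 32)) {
  stopifnot(all(c("time_h", "oscillator", "phase_rad") %in% names(data)))
  d <- data[data$time_h >= discard_h, ]
  if (length(unique(d$oscillator)) < 2) stop("need at least 2 oscillators")
  op <- d |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(R = Mod(mean(exp(1i * .data$phase_rad))), .groups = "drop")
  sigcol <- if ("x" %in% names(d)) NULL else "cosphase"
  if (!is.null(sigcol)) d$x <- cos(d$phase_rad)
  periods <- d |>
    dplyr::group_by(.data$oscillator) |>
    dplyr::group_modify(~ estimate_period(.x, band = band, signal = x)) |>
    dplyr::ungroup()
  list(order_parameter = op, mean_R = mean(op$R),
       period_sd_h = stats::sd(periods$period_h, na.rm = TRUE),
       periods = periods)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
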