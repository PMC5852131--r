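# Rhythm metrics: detrending, FFT period, RMS amplitude, chi-squared
# periodogram, developmental fit, bootstrap correlation, synchrony metrics.

make_wave <- function(period = 24, days = 10, dt = 0.25, amp = 1, phase = 0,
                      trend = 0, damping = 0) {
  t <- seq(0, days * 24 - dt, by = dt)
  tibble::tibble(time_h = t,
                 signal = trend * t + amp * exp(-damping * t) * sin(2 * pi * t / period + phase))
}

test_that("detrending removes slow baselines and preserves the oscillation", {
  d <- make_wave(trend = 0.05)
  dd <- detrend_signal(d)
  expect_lt(abs(mean(dd$signal)), 0.02)
  pure <- make_wave()$signal
  core <- seq(100, nrow(d) - 100)   # away from edge effects
  expect_lt(sqrt(mean((dd$signal - pure)[core]^2)) / sqrt(mean(pure^2)), 0.02)
  # constant signal maps to zero; zero-mean sinusoid is left nearly unchanged
  const <- tibble::tibble(time_h = d$time_h, signal = 7)
  expect_equal(detrend_signal(const)$signal, rep(0, nrow(const)))
  d0 <- detrend_signal(make_wave())
  expect_lt(max(abs(d0$signal - pure)[core]), 0.02)
  expect_error(detrend_signal(make_wave(days = 0.5), window_h = 24), "shorter")
})

test_that("FFT period estimator is unbiased to < 0.05 h on noiseless signals", {
  for (P in c(22, 23.5, 24, 25, 26, 27)) {
    est <- estimate_period(make_wave(period = P))
    expect_true(est$rhythmic)
    expect_equal(est$period_h, P, tolerance = 0.05 / P)
  }
  damped <- estimate_period(make_wave(period = 23.5, damping = 0.01))
  expect_equal(damped$period_h, 23.5, tolerance = 0.1 / 23.5)
})

test_that("white noise is flagged arrhythmic", {
  withr::with_seed(11, {
    noise <- tibble::tibble(time_h = seq(0, 239.75, by = 0.25),
                            signal = stats::rnorm(960))
  })
  est <- estimate_period(noise)
  expect_false(est$rhythmic)
  expect_true(is.na(est$period_h))
})

test_that("RMS amplitude matches closed forms and refuses short records", {
  expect_equal(rms_amplitude(make_wave(amp = 3), detrend = FALSE), 3 / sqrt(2),
               tolerance = 0.01)
  # detrending leaves a small partial-window residual at the record edges
  expect_equal(rms_amplitude(make_wave(amp = 3)), 3 / sqrt(2), tolerance = 0.02)
  zero <- tibble::tibble(time_h = seq(0, 240, 0.25), signal = 0)
  expect_equal(rms_amplitude(zero, detrend = FALSE), 0)
  # damped sinusoid against the analytic integral oracle
  gam <- 0.008; a <- 2; Tw <- 240
  d <- make_wave(amp = a, damping = gam)
  oracle <- sqrt(stats::integrate(function(t) a^2 * exp(-2 * gam * t) *
                                    sin(2 * pi * t / 24)^2, 0, Tw)$value / Tw)
  expect_equal(rms_amplitude(d, detrend = FALSE), oracle, tolerance = 0.01)
  expect_error(rms_amplitude(make_wave(days = 5), days = 10), "refusing")
})

test_that("chi-squared periodogram recovers known periods", {
  pg <- chisq_periodogram(synth_event_series(period_h = 23.7, days = 10, seed = 1))
  expect_true(pg$significant)
  expect_equal(pg$best_period_h, 23.7, tolerance = 0.1 / 23.7)
  # perfectly periodic impulse train
  t <- seq(0, 10 * 24 - 0.1, by = 0.1)
  imp <- tibble::tibble(bin_start_h = t, count = as.integer(t %% 24 == 0))
  pgi <- chisq_periodogram(imp)
  expect_equal(pgi$best_period_h, 24)
  # degenerate inputs
  expect_false(chisq_periodogram(tibble::tibble(bin_start_h = t, count = 0L))$significant)
  expect_error(chisq_periodogram(synth_event_series(days = 3)), "7 days")
  expect_equal(nrow(tidy(pg)), 81)
  expect_true(glance(pg)$significant)
})

test_that("developmental fit recovers generating parameters", {
  exact <- fit_development(synth_development(noise_sd = 0))
  expect_equal(unname(exact$estimates), c(1.58, 9.47, 23.41), tolerance = 1e-6)
  expect_false(exact$degenerate)
  noisy <- fit_development(synth_development(noise_sd = 0.2, seed = 4))
  expect_equal(unname(noisy$estimates["tau_c"]), 9.47, tolerance = 0.25)
  td <- tidy(noisy)
  expect_setequal(td$term, c("a", "tau_c", "c"))
  expect_true(all(td$std.error > 0))
  # constant periods: amplitude indistinguishable from zero -> degenerate flag
  flat <- tibble::tibble(age_days = rep(c(0, 7, 14, 28), each = 5),
                         period_h = 24 + withr::with_seed(5, stats::rnorm(20, 0, 0.05)))
  ff <- tryCatch(fit_development(flat), error = function(e) NULL)
  if (!is.null(ff)) expect_true(ff$degenerate)
  expect_error(fit_development(tibble::tibble(age_days = c(0, 7, 7, 7),
                                              period_h = c(25, 24, 24, 24))),
               "4 distinct ages")
})

test_that("bootstrap correlation behaves at the anticorrelated and null extremes", {
  perfect <- tibble::tibble(period_h = 1:20, rms_amplitude = 40 - (1:20))
  res <- period_amplitude_correlation(perfect, n_boot = 500, seed = 1)
  expect_equal(res$r, -1)
  expect_lt(res$p_value, 1e-10)
  withr::with_seed(6, {
    null <- tibble::tibble(period_h = stats::rnorm(200), rms_amplitude = stats::rnorm(200))
  })
  rn <- period_amplitude_correlation(null, n_boot = 1000, seed = 2)
  expect_lt(abs(rn$r), 0.2)
  expect_gt(rn$p_value, 0.05)
  # size-controlled resampling still recovers the generating sign
  withr::with_seed(7, {
    x <- stats::rnorm(120)
    gen <- tibble::tibble(period_h = x, rms_amplitude = -0.5 * x + stats::rnorm(120, 0, 1))
  })
  rs <- period_amplitude_correlation(gen, n_boot = 2000, size_control_n = 58, seed = 3)
  expect_lt(rs$boot_mean + 2 * rs$boot_sem, 0)
  expect_equal(rs$boot_mean, stats::cor(gen$period_h, gen$rms_amplitude),
               tolerance = 0.1)
  expect_error(period_amplitude_correlation(perfect[1:5, ]), "at least 10")
  expect_error(period_amplitude_correlation(
    tibble::tibble(period_h = rep(1, 12), rms_amplitude = 1:12)), "zero variance")
})

test_that("synchrony metrics track the order parameter and period dispersion", {
  t <- seq(0, 240, 0.25)
  same <- tidyr::expand_grid(oscillator = 1:5, time_h = t) |>
    dplyr::mutate(phase_rad = 2 * pi * time_h / 24)
  sm <- sync_metrics(same)
  expect_equal(sm$order_parameter$R, rep(1, length(t)))
  expect_lt(sm$period_sd_h, 0.01)
  # uniform random phases: R ~ 1/sqrt(n)
  withr::with_seed(8, {
    n <- 400
    rand <- tibble::tibble(time_h = 0, oscillator = seq_len(n),
                           phase_rad = stats::runif(n, 0, 2 * pi))
  })
  R1 <- Mod(mean(exp(1i * rand$phase_rad)))
  expect_lt(R1, 3 / sqrt(n))
  # removing coupling drops the order parameter and raises period SD
  sim <- default_chain_sims()[[1]]
  spec0 <- chain_network(60, q = 0, period = sim$tau)
  traj0 <- simulate_network(spec0, days = 12, seed = 91)
  s_on <- sync_metrics(sim$traj, discard_h = 48)
  s_off <- sync_metrics(traj0, discard_h = 48)
  expect_gt(s_on$mean_R, s_off$mean_R)
  expect_lt(s_on$period_sd_h, s_off$period_sd_h)
})
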