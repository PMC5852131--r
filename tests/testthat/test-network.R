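# Coupled chains and grids: topology construction, mean-field predictions,
# and ensemble observables.

test_that("chain topology has open boundaries and the calibrated default K", {
  spec <- chain_network(3, K = 1, q = 1, period = 24)
  expect_equal(mean_field(spec)$k_in, c(1, 2, 1))
  expect_true(all(diag(spec$coupling) == 0))
  # q = 0 is the uncoupled control
  expect_equal(mean_field(chain_network(5, K = 1, q = 0))$k_in, rep(0, 5))
  expect_error(chain_network(1), "at least 2")
  # default calibration: interior input 2*q*K reproduces the 23.5 h target
  K <- calibrate_coupling()
  expect_equal(K, 0.0020970, tolerance = 1e-4)
  spec10 <- chain_network(60, q = 10, period = 25.5)
  mf <- mean_field(spec10)
  expect_equal(mf$k_in[30], 2 * 10 * K)
  expect_equal(mf$period_h[30], 23.5, tolerance = 1e-10)
  expect_equal(mf$r_star[30], 2 * 10 * K / 0.02 + 1)
  expect_error(calibrate_coupling(twist = 0), "zero twist")
})

test_that("mean-field prediction is sign-symmetric in the twist", {
  neg <- mean_field(chain_network(10, K = 0.002, q = 10, twist = -0.01, period = 25.5))
  pos <- mean_field(chain_network(10, K = 0.002, q = 10, twist = +0.01, period = 25.5))
  w0 <- 2 * pi / 25.5
  expect_equal(neg$omega_prime - w0, -(pos$omega_prime - w0))
  expect_equal(neg$r_star, pos$r_star)
})

test_that("grid neighbourhoods follow the von Neumann / radius / mask rules", {
  g <- grid_network(3, 3, K = 1, q = 1)
  deg <- rowSums(g$coupling > 0)
  corner <- g$geometry$oscillator[g$geometry$row %in% c(1, 3) & g$geometry$col %in% c(1, 3)]
  center <- g$geometry$oscillator[g$geometry$row == 2 & g$geometry$col == 2]
  expect_true(all(deg[corner] == 2))
  expect_equal(deg[center], 4)
  expect_true(all(sort(unique(deg)) == c(2, 3, 4)))
  # the 0.5 prefactor of the 2D coupling is baked into the matrix
  expect_equal(unique(g$coupling[g$coupling > 0]), 0.5)
  expect_true(isSymmetric(g$coupling))
  # radius 1.5 gives the 8-neighbourhood
  g8 <- grid_network(5, 5, scheme = "radius", radius = 1.5, K = 1)
  inner <- g8$geometry$oscillator[g8$geometry$row == 3 & g8$geometry$col == 3]
  expect_equal(sum(g8$coupling[inner, ] > 0), 8)
  # elongated leaf-like mask: medial cells outnumber boundary neighbours
  mask <- matrix(FALSE, 5, 12)
  mask[2:4, 2:11] <- TRUE
  gm <- grid_network(mask = mask, K = 1)
  degm <- rowSums(gm$coupling > 0)
  medial <- gm$geometry$row == 3 & gm$geometry$col %in% 3:10
  expect_true(min(degm[medial]) > min(degm[!medial]))
  expect_error(grid_network(mask = matrix(FALSE, 2, 2)), "empty mask")
})

test_that("an uncoupled network reproduces single-cell closed forms", {
  spec <- chain_network(4, K = 0.002, q = 0, period = c(23, 24, 25, 26))
  phi0 <- c(0, 1, 2, 3)
  traj <- simulate_network(spec, t_end = 100, dt = 0.5,
                           init = tibble::tibble(x = 0.5 * cos(phi0), y = 0.5 * sin(phi0)))
  for (i in 1:4) {
    p <- osc_params(period = c(23, 24, 25, 26)[i])
    tr <- traj[traj$oscillator == i, ]
    expect_lt(max(abs(tr$r - radial_solution(p, 0.5, tr$time_h))), 1e-6)
    expect_lt(max(abs(tr$phase_rad - phase_solution(p, 0.5, phi0[i], tr$time_h))), 1e-4)
  }
})

test_that("a one-cell network equals the single-oscillator integrator", {
  p <- osc_params(period = 24.7)
  a <- integrate_oscillator(p, r0 = 0.8, phi0 = 0.2, t_end = 48, dt = 0.25)
  spec <- chain_network(2, K = 1, q = 0, period = 24.7)  # q = 0: no interaction
  b <- simulate_network(spec, t_end = 48, dt = 0.25,
                        init = tibble::tibble(x = 0.8 * cos(c(0.2, 0.2)),
                                              y = 0.8 * sin(c(0.2, 0.2))))
  expect_equal(a$x, b$x[b$oscillator == 1], tolerance = 1e-9)
})

test_that("coupled chain at q = 10 matches its mean-field prediction", {
  sim <- default_chain_sims()[[1]]
  mf <- mean_field(sim$spec)
  interior <- 21:40
  # ensemble period within 0.3 h of the interior mean-field period
  expect_lt(abs(ensemble_period(sim$traj) - mean(mf$period_h[interior])), 0.3)
  # interior stationary radii within 15% of K_i/lambda + A
  late <- sim$traj |>
    dplyr::filter(.data$time_h >= 200) |>
    dplyr::group_by(.data$oscillator) |>
    dplyr::summarise(rbar = mean(.data$r))
  rel <- abs(late$rbar[interior] - mf$r_star[interior]) / mf$r_star[interior]
  expect_lt(max(rel), 0.15)
})

test_that("the chain centre expands and phase-leads under negative twist", {
  sim <- default_chain_sims()[[2]]
  late <- sim$traj |>
    dplyr::filter(.data$time_h >= 200) |>
    dplyr::group_by(.data$oscillator) |>
    dplyr::summarise(rbar = mean(.data$r))
  centre <- 25:36; edge <- c(1:4, 57:60)
  expect_gt(mean(late$rbar[centre]), mean(late$rbar[edge]))
  for (cyc in 2:3) {
    m <- suppressWarnings(peak_phase_map(sim$traj, cycle = cyc))
    cen <- m$phase_rad[m$col >= 21 & m$col <= 40]
    edg <- m$phase_rad[m$col <= 10 | m$col >= 51]
    d <- circular_distance(circular_mean(cen)$mean_rad, circular_mean(edg)$mean_rad)
    expect_lt(d, 0)  # centre peaks earlier: phase lead
  }
})

test_that("ensemble_signal aggregates as stated", {
  p <- osc_params()
  traj <- integrate_oscillator(p, r0 = 1, t_end = 48, dt = 0.5)
  expect_equal(ensemble_signal(traj, mode = "mean")$signal, traj$x)
  two <- traj |> dplyr::mutate(oscillator = 2L) |> dplyr::bind_rows(traj)
  expect_equal(ensemble_signal(two, mode = "sum")$signal, 2 * traj$x)
  expect_equal(ensemble_signal(traj, scale = 50)$signal, 50 * traj$x)
})

test_that("a desynchronized ensemble has lower RMS than a synchronized one", {
  sims <- default_chain_sims()[[3]]
  spec0 <- chain_network(60, q = 0, period = sims$tau)
  traj0 <- simulate_network(spec0, days = 12, seed = 77)
  sync_sig <- ensemble_signal(sims$traj); sync_sig <- sync_sig[sync_sig$time_h >= 48, ]
  desync_sig <- ensemble_signal(traj0); desync_sig <- desync_sig[desync_sig$time_h >= 48, ]
  expect_gt(rms_amplitude(sync_sig), rms_amplitude(desync_sig))
})

test_that("identical seeds give bit-identical sweep tables", {
  a <- dose_response_sweep(q = c(0, 10), n = 16, n_replicates = 2, seeds = 1:2,
                           days = 8)
  b <- dose_response_sweep(q = c(0, 10), n = 16, n_replicates = 2, seeds = 1:2,
                           days = 8)
  expect_identical(a, b)
  expect_error(dose_response_sweep(seeds = c(1, 1), n_replicates = 2), "Duplicated")
})
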