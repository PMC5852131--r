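# twistclock

Tools for modelling and analysing strongly synchronized circadian oscillator
networks, motivated by non-neuronal brain tissues such as the choroid plexus,
whose epithelial cells keep near-perfect phase synchrony through local
(gap-junction-like) coupling. The package is aimed at chronobiologists and
modellers who work with bioluminescence reporter recordings (PER2::LUC-style
photomultiplier time series in kcpm, thousand photon counts per minute) and
want to connect tissue-level period, amplitude and spatial phase patterns to
a mechanistic single-cell model.

## The model and the statistics

**Single cell.** Each cellular clock is a modified Poincaré oscillator in
polar coordinates (r, φ):

    dr/dt = λ r (A − r)
    dφ/dt = ω + ε (A − r),        ω = 2π/τ

with limit-cycle amplitude A, radial relaxation rate λ (1/h), intrinsic
period τ (h), and twist ε (1/h). The twist couples amplitude to speed:
ε < 0 means an amplitude excess transiently *accelerates* the oscillation.
The radial and phase equations solve in closed form, and the isochron
(asymptotic phase) of any state (r₀, φ₀) is φ₀ + (ε/λ)·log(A/r₀); both are
implemented and cross-validated against the numerical integrator.

**Network.** Cells couple additively in Cartesian coordinates to their
nearest neighbours (chain with open boundaries, or 2D von Neumann / radius /
masked grids), scaled by an integer multiplier q that emulates graded
gap-junction blockade (q = 0 blocked, q = 10 full coupling). Near synchrony
the mean field predicts, for summed coupling input K_i:

    r*  ≈ K_i/λ + A            (amplitude expansion)
    ω′  = ω − ε K_i/λ          (period shortening when ε < 0)

Interior cells receive more input than boundary cells, so the tissue centre
expands more and — under negative twist — phase-leads, which is the
mechanism the spatial statistics quantify.

**Analysis.** `estimate_period()` (interpolated FFT), `rms_amplitude()`
(equal-duration RMS over 10 days), `chisq_periodogram()` (Sokolove–Bushell),
`mra_decompose()` / `rhythmicity_score()` (discrete-wavelet multiresolution
band variances: circadian detail D6, 16–32 h, against noise detail D1,
0.5–1 h, cohort-normalized), `morans_i()` (circular-variable Moran's I,
angular and complex-embedding variants, Monte-Carlo permutation p-values),
`period_amplitude_correlation()` (bootstrap Pearson R with z-test and
size-controlled resampling), and `fit_development()` (exponential maturation
fit period = a·e^(−t/τ_c) + c). Seeded generators in `synth_*()` produce
every input the pipeline consumes.

## Worked example

Simulate the default 60-cell negative-twist chain at full coupling
(intrinsic periods ~ N(25.5 h, 1 h), initial phase SD 1 h, K calibrated from
the mean field), then estimate its ensemble rhythm and phase patterning:

```r
library(twistclock)

spec <- chain_network(n = 60, q = 10, period = draw_periods(60, seed = 1))
traj <- simulate_network(spec, days = 12, phase_sd_h = 1, seed = 10001)
sig  <- ensemble_signal(traj)
estimate_period(sig[sig$time_h >= 48, ])
#> # A tibble: 1 × 4
#>   period_h   power     snr rhythmic
#>      <dbl>   <dbl>   <dbl> <lgl>
#> 1     23.6 473447. 3.79e12 TRUE

mean_field(spec)[30, ]      # interior-cell prediction
#> # A tibble: 1 × 5
#>   oscillator   k_in r_star omega_prime period_h
#>        <int>  <dbl>  <dbl>       <dbl>    <dbl>
#> 1         30 0.0440   3.20       0.264     23.8

m <- peak_phase_map(traj, cycle = 2)
morans_i(m, n_perm = 999, seed = 7)
#> # A tibble: 1 × 8
#>   statistic variant p_value n_perm null_mean null_sd     n degenerate
#>       <dbl> <chr>     <dbl>  <dbl>     <dbl>   <dbl> <int> <lgl>
#> 1     0.626 angular   0.001    999   -0.0153   0.141    54 FALSE
```

The coupled ensemble runs at ~23.6 h — about two hours faster than the mean
intrinsic period, as the mean field predicts for negative twist — and the
peak-phase map of the second cycle is strongly spatially autocorrelated
(I = 0.63 against a permutation null mean of ≈ −1/(N−1)), reflecting the
centre-leading phase gradient. `autoplot()` methods exist for trajectories,
periodograms, dose-response sweeps and phase maps, and `tidy()`/`glance()`
for the fitted objects.

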