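---
title: "Twist oscillator networks: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twist oscillator networks: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 3.5)
library(twistclock)
library(dplyr)
```

This vignette is the package's own account of the science it implements: the
single-cell model and its closed forms, the coupled-network mechanism, what
each estimator assumes, what the synthetic-data generators do and do not
emulate, and the numerical and design choices that were genuinely open.

## The single-cell model

A cellular circadian clock is represented by a modified Poincaré oscillator,

$$\frac{dr}{dt} = \lambda\, r\,(A - r), \qquad
  \frac{d\varphi}{dt} = \omega + \varepsilon\,(A - r),$$

with four parameters: the limit-cycle amplitude $A$ (dimensionless; the
package default is 1), the radial relaxation rate $\lambda$ (1/h; default
0.02, i.e. a relaxation time $1/(\lambda A) = 50$ h, consistent with the
slowly damping rhythms of tissue explants), the intrinsic period $\tau$
(h; $\omega = 2\pi/\tau$), and the twist $\varepsilon$ (1/h; default
$-0.01$). The twist is the model's essential ingredient: it makes the
instantaneous angular velocity depend linearly on the radial deviation from
the cycle, so that under negative twist an oscillator pushed *above* its
steady-state amplitude transiently runs *fast*. This is what lets coupling —
which expands amplitudes — shorten the period of a synchronized tissue.

Both equations solve in closed form (`radial_solution()`,
`phase_solution()`), and the isochron label of a state is analytic:
`asymptotic_phase()` returns $\varphi_0 + (\varepsilon/\lambda)\log(A/r_0)$.
Without twist, isochrons are straight radial lines; with twist they bend.
The test suite uses the closed forms as oracles for the numerical
integrator and vice versa.

```{r isochron}
p <- osc_params()                 # A = 1, lambda = 0.02, twist = -0.01, 24 h
asymptotic_phase(p, r0 = 0.5)     # a sub-amplitude state is phase-advanced
```

### Numerical choices

Integration is performed in Cartesian coordinates (the polar form is
singular at $r = 0$, which is a legitimate fixed point) with `deSolve`'s
lsoda at `rtol = 1e-8`, `atol = 1e-10`. These tolerances out-resolve the
closed-form comparison bounds used in the tests ($10^{-6}$ on radius,
$10^{-4}$ rad on phase over 200 h). Phases are kept cumulative (unwrapped)
internally; wrapping happens only at statistics boundaries. The closed-form
operations reject $r_0 \le 0$ (log singularity); the integrator accepts
$r_0 = 0$.

## Coupled networks and the mean field

Cells couple additively on both Cartesian coordinates. A chain of $N$ cells
has open boundaries — end cells receive input from one neighbour, interior
cells from two — and an integer multiplier $q$ scales the coupling constant
$K$, emulating graded pharmacological blockade ($q = 0,\dots,10$). On 2D
grids the coupling term is $0.5\sum_j K_{ij} x_j$ over the von Neumann
neighbourhood (or all lattice neighbours within a chosen radius), with an
optional boolean mask for tissue-like geometries.

Near synchrony the radial equation closes to give, for summed input
$K_i = q\sum_j K_{ij}$,

$$r_i^\ast \approx K_i/\lambda + A, \qquad
  \omega_i' = \omega_i - \varepsilon K_i / \lambda .$$

`mean_field()` tabulates both per oscillator. Two consequences drive all
package-level behaviour: amplitudes expand with coupling regardless of the
twist sign, and the frequency shifts only through the twist — negative
twist shortens the synchronized period, positive twist lengthens it
symmetrically, zero twist leaves it at the (frequency-averaged) intrinsic
value. Because interior cells receive roughly double the boundary input,
the tissue centre expands more and, under negative twist, phase-leads the
edges at every cycle peak.

### Parameter defaults and calibration

The defaults state the study conditions the package simulates: $A = 1$,
$\lambda = 0.02$ h⁻¹, $\varepsilon = -0.01$ h⁻¹, intrinsic periods drawn
from $\mathcal N(25.5\,\mathrm h, 1\,\mathrm h)$ (truncated at $\pm 4$ SD to
avoid pathological draws), initial phases with 1 h SD, and a chain length of
$N = 60$ — large enough that interior cells dominate the locked frequency,
cheap enough to integrate in seconds. The coupling constant is not free:
`calibrate_coupling()` inverts the mean-field frequency shift for an
interior cell so that the fully coupled chain ($q = 10$) runs at 23.5 h when
the mean intrinsic period is 25.5 h, giving $K = 0.0020970$ h⁻¹. This is a
deterministic, documented replacement for a by-hand tuning step; only the
magnitude of the twist enters, so the same $K$ serves the sign-flipped
control simulations. Simulations discard a 48 h transient before estimating
periods and amplitudes — the single-cell relaxation time is 50 h but
coupling compresses it, and the fixtures confirm 48 h suffices.

`dose_response_sweep()` repeats the simulation over $q$ and seeded replicate
draws, and gates the reported ensemble period on a time-averaged Kuramoto
order parameter of at least 0.6: an "ensemble period" presumes a
synchronized ensemble, and weakly coupled runs are flagged rather than
silently averaged. Whether the ensemble photometric proxy is the mean or the
sum of oscillators is a scale convention only; the package defaults to the
mean.

```{r meanfield}
mean_field(chain_network(60, q = 10, period = 25.5))[30, ]
```

## Rhythm estimators

**Period.** `estimate_period()` detrends with a 24 h centred running mean,
applies a Hann window, zero-pads eightfold, and refines the largest spectral
peak inside 16–32 h by local quadratic interpolation of the log-magnitude. A
10-day record has a raw bin spacing of roughly 2.4 h near 24 h, so the
refinement is what makes sub-0.05 h accuracy possible; the suite verifies
bias below 0.05 h across 22–27 h on noiseless signals. A record is declared
arrhythmic when the in-band peak power is less than five times the median
out-of-band power — an explicit, testable convention for an otherwise
unstated criterion.

**Amplitude.** `rms_amplitude()` takes the RMS of the first ten days. It
detrends by default (photomultiplier baselines drift); a raw mode is kept
because paired designs use amplitude *ratios*, for which the choice largely
cancels. Detrending with partial windows at the record edges leaves a
residual of order 1–2% on a pure sinusoid, which the tests account for.

**Event series.** `chisq_periodogram()` implements the Sokolove–Bushell
statistic on 6-min bins, scanning 20–28 h at 0.1 h steps. Each candidate
period has an asymptotically exact $\chi^2_{P-1}$ p-value; scan-level
significance applies a Bonferroni correction, so the full-scan false-alarm
rate is controlled at (conservatively below) $\alpha$ while the per-period
test stays calibrated. The suite checks both properties on a Poisson null.

**Wavelet rhythmicity.** `mra_decompose()` computes a maximal-overlap
discrete wavelet (Daubechies db4) multiresolution decomposition. At 15-min
sampling, detail $D_6$ spans 16 h to just under 32 h (the circadian band)
and $D_1$ spans 0.5–1 h (the noise band). The series is extended by
reflection before the circular transform, and the first and last day of
every detail are truncated before band variances are computed, suppressing
edge artefacts. `rhythmicity_score()` ratios the cohort-normalized circadian
and noise shares; the score is *cohort-relative* by construction — it ranks
tissues within the supplied set and is not comparable across cohorts. The
wavelet family and boundary rule are conventions (recorded in the output);
the tests therefore assert ordering and invariance properties rather than
absolute score values, plus agreement of the raw decomposition with an
external wavelet implementation on a fixed fixture.

**Correlation.** `period_amplitude_correlation()` reports the Pearson R of
(period, amplitude) pairs with a bootstrap mean and SEM over 10,000
resamples and a z-test; the optional size-controlled mode draws a fixed
number of pairs per resample without replacement, so cohorts of unequal
size can be compared at matched power.

**Development.** `fit_development()` fits
$\text{period} = a\,e^{-t/\tau_c} + c$ by Levenberg–Marquardt from several
data-driven starting points, returns the parameter covariance, and flags
fits whose amplitude is indistinguishable from zero (flat data leave
$\tau_c$ unidentifiable).

## Spatial statistics

`morans_i()` offers two circular variants of Moran's I under binary,
symmetric nearest-neighbour weights (the natural structure for
gap-junction coupling): the *angular* form applies the classical statistic
to signed circular deviations $d_\theta(X_i, \bar X)$ from the circular
mean, and the *circular* form embeds phases on the unit circle and computes
the complex analogue, reporting the real part (the imaginary part is
attached for inspection, since the formula is complex-valued in general and
no convention fixes which part is "the" statistic). Both have permutation
expectation $-1/(N-1)$ and agree in sign on gradients and checkerboards.
Significance is by Monte-Carlo relabelling of phases over positions,
one-sided for positive autocorrelation by default (the scientific claim is
positive patterning); $p$-resolution is $1/(n_{\mathrm{perm}}+1)$. Fully
synchronized maps make both formulas 0/0 and return a degeneracy flag
instead of a number. `peak_phase_map()` converts a simulated trajectory into
a phase map by locating each unit's (quadratically refined) peak within one
post-transient cycle window; units without an interior peak are excluded and
the weights rebuilt.

## Synthetic data: what it does and does not emulate

The generators produce damped ~24 h oscillations at 20–150 kcpm with slow
linear trends and either additive Gaussian noise (SD defaulting to 3% of
the amplitude, a photomultiplier shot-noise proxy) or shot-like noise with
SD scaling as the square root of the instantaneous signal; paired
left/right designs sharing one seeded parameter draw with the manipulation
(coupling reduction, or cutting into independent sub-chains) applied to one
side only; developmental (age, period) tables following
$1.58\,e^{-t/9.47} + 23.41$ h; gradient/random/checkerboard phase maps; and
rhythmic or flat Poisson event series. They deliberately do *not* emulate
real recordings' full noise spectra (1/f components, re-feeding transients,
position drift) or 2D bioluminescence movies — grids are emitted as
per-cell series. Passing tests therefore demonstrate that the estimators
recover known structure under the stated noise model, not that they are
robust to every artefact of real photometry; the day-truncation and
arrhythmicity guards are the package's concessions to the latter.

The checkerboard fixture alternates two phases $\pi/2$ apart rather than
antipodal ones: exactly antipodal phases have zero circular resultant, so
the circular mean — and with it the angular statistic — would be undefined.

## Problem sizes used in the shipped checks

The automated checks simulate 60-cell chains for 12 days at 15-min
sampling (5 replicate draws), sweep $q \in \{0, 2, 4, 6, 8, 10\}$ over 5
seeds for each twist sign, calibrate the periodogram on 200 seeded 7-day
Poisson nulls and the Monte-Carlo Moran p-values on 400 seeded 30-unit
maps with 199 permutations each. These sizes were chosen so that every
stochastic assertion sits several standard errors from its threshold while
the whole suite runs in about a minute.

## Known limitations

The model is the simplest amplitude–phase oscillator with a *linear*
amplitude–frequency law; nonlinear twist, delay or stochastic (Langevin)
dynamics, and parameter inference from recorded data are out of scope. The
mean-field predictions degrade near boundaries (the tests allow 15% on
interior radii and 0.3 h on the locked period). The rhythmicity score
requires a cohort and a nonzero noise floor; noiseless synthetic input is
rejected rather than regularized.
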