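Package: twistclock
Title: Coupled Twist-Oscillator Networks and Circadian Rhythm Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling and analysing strongly synchronized circadian
    oscillator networks such as the choroid plexus. Implements the modified
    Poincare (twist) oscillator with closed-form solutions and analytic
    isochrons, nearest-neighbour coupled chains and grids with mean-field
    predictions, FFT-based period and RMS amplitude estimation of
    bioluminescence time series, the Sokolove-Bushell chi-squared periodogram,
    a discrete-wavelet multiresolution rhythmicity score, circular-variable
    Moran's I spatial autocorrelation with Monte-Carlo significance, bootstrap
    period-amplitude correlation, and seeded synthetic-data generators that
    emulate photomultiplier recordings of tissue explants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
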