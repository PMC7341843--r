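Package: circawave
Title: Spatiotemporal Analysis of Circadian Imaging, Electrophysiology and
    Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for circadian recordings of the suprachiasmatic
    nucleus (SCN) and of circadian behaviour: phase mapping of bioluminescence
    and fluorescence time-lapse movies over a grid of regions of interest,
    centre-of-luminescence wave trajectories and their excursion-area
    statistic, Rayleigh circular statistics of oscillator phase, FFT-seeded
    nonlinear least-squares rhythm fitting (period, amplitude, relative
    amplitude error, goodness of fit), the revised local-variation (LvR)
    spike-train regularity statistic, optogenetic phase-response curves from
    pre/post-stimulation peak extrapolation, and wheel-running actogram
    profiling (chi-square periodogram, nonparametric relative amplitude,
    onset-aligned activity profiles). Includes seeded synthetic-data
    generators with exact ground truth for every recording modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
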