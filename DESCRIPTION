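Package: pepix
Title: Simulation and Reconstruction for Pixel-Wise Programmable-Exposure Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for studying image sensors whose pixels have individually
    programmable exposure duration and phase, in the context of high-speed
    fluorescence voltage imaging. Generates ground-truth genetically encoded
    voltage indicator (GEVI) signals as double-exponential spike waveforms,
    simulates pixel sampling as box-kernel exposure integration with Poisson
    shot noise and exposure-dependent Gaussian read noise, provides an
    analytic model of peak spike signal-to-noise ratio versus exposure
    duration, analyzes the aliased spectra of phase-staggered pixel ensembles,
    reconstructs high-rate region-of-interest time series from staggered
    low-rate pixels by ridge regression or merge-and-interpolate, and detects
    putative spiking events with the associated noise-estimation and
    event-matching procedures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
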