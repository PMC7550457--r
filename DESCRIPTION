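Package: nirsynth
Title: Semi-Simulated Ground Truth for Functional Near-Infrared Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building ground-truth benchmarks for functional
    near-infrared spectroscopy (fNIRS) signal processing. Simulates
    resting-state-like multimodal continuous-wave recordings (long- and
    short-separation channels, cardiac, Mayer-wave and respiratory
    physiology, accelerometer and photoplethysmography auxiliaries),
    injects calibrated synthetic gamma-shaped hemodynamic responses into
    simulated or real recordings in the intensity domain, reads and writes
    the SNIRF v1.0 (HDF5) interchange format including per-channel
    ground-truth flags, assesses data quality (channel signal-to-noise
    ratio in dB, motion-artifact ratio), and recovers injected responses
    with block averaging or a general linear model with Gaussian temporal
    bases, polynomial drift and short-separation nuisance regression via
    the modified Beer-Lambert law.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rhdf5,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
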