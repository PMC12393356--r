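Package: bursttrack
Title: Transcriptional Burst Calling and Chromatin Locus Mobility from Live-Cell Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline linking transcriptional bursting to
    chromatin locus mobility and single-molecule receptor states in live-cell
    movies. Provides synthetic-movie and track simulators with known ground
    truth (Brownian, confined, and fractional-Brownian walkers; telegraph
    burst kinetics; rigid stage drift), per-frame nucleus and spot
    segmentation with a per-nucleus difference-of-Gaussians burst statistic,
    linear-assignment particle linking with gap closing, rigid-body drift
    correction, per-track diffusion biophysics (MSD, anomalous exponent,
    confinement radius, residence times), Gaussian-mixture and Ward+SVM
    track-state clustering with per-condition fold changes, burst-state
    mobility comparisons, and signed-distance organelle proximity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    clue,
    cluster,
    dplyr,
    generics,
    ggplot2,
    kernlab,
    mclust,
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
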