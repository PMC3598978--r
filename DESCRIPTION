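Package: cardiocirc
Title: Circadian Heart-Rate Modelling and Virtual QT Trial Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and simulates an age- and sex-dependent circadian model of
    the beat-to-beat RR interval. Log-transformed RR is regressed on age,
    age squared, sex, and a single 24-hour sine/cosine harmonic with
    sex-specific amplitude; within-subject temporal dependence of the
    residuals is captured by a high-order autoregressive process. The
    package provides cluster-robust inference for the regression,
    backward elimination from an hourly-dummy preliminary model, a
    reproducible RR simulator for virtual subjects and cohorts, and a
    virtual thorough-QT trial layer: Hill-equation channel inhibition,
    Fridericia QTc correction, a pluggable QT engine with a surrogate
    default, and single-point versus individualised delta-QTcF baseline
    corrections. Synthetic dense (beat-level) and sparse (ambulatory)
    cohort generators with known ground truth support end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
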