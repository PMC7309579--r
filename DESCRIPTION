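Package: ipscfit
Title: Kinetic Modelling and Fitting of Inhibitory Postsynaptic Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing GABA-A receptor mediated inhibitory
    postsynaptic currents (IPSCs) with a kinetic model of gephyrin-dependent
    transsynaptic signalling. Provides the closed-form and ODE solutions of
    the model, a synthetic-data generator for voltage-clamp recordings
    (single events, Poisson event trains, multi-condition datasets with
    pseudo-Voigt peak-amplitude distributions), scaled sliding-template
    event detection, multi-start derivative-free fitting of the ten model
    parameters to individual events with RMSE-based acceptance, screening of
    day-to-day control variability, rank-based multi-group comparison with
    Dunn's post-hoc procedure, effect classification, and cross-validated
    classification of events from their fitted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    deSolve,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
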