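Package: icpfr
Title: Classification of Intracranial Pressure-Flow Regimes from Multimodal Neuromonitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the relationship between cerebral perfusion
    pressure and brain-tissue perfusion in continuous neurocritical-care
    monitoring data. Provides a seeded synthetic generator for multimodal
    monitoring epochs (pulsatile arterial pressure, intracranial pressure,
    thermodiffusion perfusion) with prescribed pressure-flow coordination;
    quality-control filtering and extraction of nominally two-hour analysis
    intervals; inversion of a two-parameter conductance/compliance
    compartmental model under non-negativity constraints to estimate cerebral
    blood flow from perfusion pressure; classification of intervals into
    positive, zero and negative pressure-flow regimes via a
    variance-standardized linear calibration slope; windowed autoregulation
    indices (Mx, PRx); and regime-level statistics including a
    two-dimensional two-sample Kolmogorov-Smirnov test, a joint-index linear
    discriminant, and automatic-relevance-determination predictor ranking.
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
    glmnet,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
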