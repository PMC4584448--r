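Package: ercnet
Title: Latent Cortical Network Structures from Spectral Causality Tensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of latent directed-network structures in trial-based
    multichannel neural recordings. Implements the full analysis chain:
    gaze-based trial screening, artifact-trial rejection, local
    stationarization, independent component analysis with restart
    aggregation, sliding-window multitrial vector autoregressive modelling
    with AIC order selection and model validation, spectral effective
    connectivity (DTF, full-frequency DTF, partial coherence, direct DTF),
    event-related causality normalized to a baseline period, ternary maps
    of significant condition contrasts under false-discovery-rate control,
    constrained PARAFAC tensor decomposition with core-consistency model
    selection, directed-graph connectivity statistics, and shuffle-based
    inference on component loadings. Ships a synthetic-data generator that
    plants band-specific, condition-dependent couplings between latent
    sources so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    signal
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
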