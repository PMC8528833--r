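Package: microcoh
Title: Microscale Brain-Network Dynamics via Ensemble Imaginary Wavelet Coherency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Time-frequency connectivity between multichannel
    electrophysiological recordings at millisecond resolution. Implements the
    analytic Morlet continuous wavelet transform with dyadic scale
    discretization, ensemble wavelet-transform coherency over event-locked
    epochs, its imaginary part (insensitive to zero-lag volume conduction),
    cone-of-influence handling, and non-parametric bootstrap significance
    against user-selected background epochs. A network layer aggregates
    significant connectivity into static and dynamic weighted graphs, computes
    ten weighted centrality measures with a PCA-based characteristic-centrality
    ranking, and supports group-level analysis (grand averages, PCA network
    modules, global connectivity effect sizes). Includes seeded synthetic-data
    generators for event-locked fixtures and EDF/EDF+ input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
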