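Package: connharm
Title: Harmonic Decomposition of Structural Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes structural connectomes into graph Laplacian harmonics
    and characterizes them across integrative, degenerate, and segregative
    regimes. Provides the degree-normalized Laplacian eigenbasis, spatial
    frequency measures (sparsity, zero-cross rate, network zero crossings,
    roughness), exact bipartite matching of subject harmonics to a consensus
    basis, inter-subject agreement profiles, eigenvalue gap-spectrum analysis
    with spline smoothing and regime detection, Rayleigh-noise perturbation
    stability, low-rank regime-specific connectome reconstruction with
    weighted graph metrics, and projection of functional time series onto
    harmonic power vectors with energy, sample entropy, harmonic diversity,
    and ternary regime dynamics. Includes a seeded synthetic-data generator
    for modular connectome ensembles, spatial adjacency, and harmonic-mixture
    time series, plus a command-line interface.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
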