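Package: reefscape
Title: Soundscape Mapping and Quantification for Passive Acoustic
    Monitoring Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Batch analysis of passive-acoustic recording campaigns, from
    raw WAV files to low-dimensional acoustic maps and quantitative
    soundscape metrics.  Recordings are high-pass filtered, cut into
    one-second segments and projected into a mel-frequency acoustic space
    (mel-spectrum, mel-spectrogram, or an external embedding adapter),
    aggregated over an integration time, pruned and robust-scaled.  The
    resulting feature matrix is embedded with an ensemble of independent
    UMAP runs whose pairwise-distance matrices are averaged; the averaged
    matrix feeds pairwise silhouette matrices between label categories,
    density-based clustering (HDBSCAN, excess-of-mass or leaf selection)
    with label contingency tables, and normalized temporal trajectory
    metrics.  Embedding-stability diagnostics (running-average
    convergence, distance-contrast IQM, local and triplet topology
    preservation) and a deterministic synthetic reef-soundscape generator
    are included, so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Rcpp,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
LinkingTo:
    Rcpp
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
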