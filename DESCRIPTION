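Package: pixtopo
Title: Topological Analysis of Greyscale Images via Cubical Persistent Homology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes persistent homology of greyscale images using cubical
    complexes (V-construction) under dual black-to-white and white-to-black
    filtrations, with explicit dimension-1 cycle representatives. Provides
    persistence landscapes, Betti curves, an Alexander-duality-violation
    statistic, grid-based topological feature maps (cycle density, maximal
    persistence, maximal cycle perimeter), gaze-fixation heatmaps and
    gaze-weighted empirical CDF comparisons (MSE, ME, Kolmogorov-Smirnov),
    together with a synthetic scene and fixation generator with known
    topological ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
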