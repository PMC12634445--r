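Package: neurodyad
Title: Dyadic Neural Similarity and Social Network Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Links inter-subject correlation (ISC) of regional fMRI time
    series, measured before people meet, to their later distance in a
    mutually-reported friendship network and to the direction of change in
    that distance. Implements the full dyadic pipeline: reciprocal-graph
    construction and geodesic social distance, the ISC similarity chain
    (spatial parcel averaging, run concatenation, Pearson correlation,
    1.5*IQR winsorization, Fisher z, per-region normalization across dyads),
    node-level permutation tests for dyadic data, Benjamini-Hochberg FDR,
    participant-level bootstrap confidence intervals, and permutation tests
    for the reduction of a group difference under covariate control. A
    synthetic-data generator with closed-form expected ISC makes every stage
    testable without any imaging data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
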