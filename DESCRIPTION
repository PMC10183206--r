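Package: flocknet
Title: Arrival-Time Social Networks and Selection on Sociality from RFID
    Feeder Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers social association networks from time-stamped RFID
    feeder detections using an arrival-time rule (co-arrival within a
    short window after an absence gap), alongside the classical
    gambit-of-the-group and time-window-overlap definitions. Builds
    Simple-Ratio-Index weighted networks, computes degree, strength,
    eigenvector centrality and opposite-sex degree, derives annual and
    lifetime fitness from a multi-generational pedigree (recruit counts
    and de-lifed individual contributions to population growth), and
    quantifies within-individual repeatability and linear plus quadratic
    (stabilizing) selection on sociality with Bayesian mixed models.
    Node-permutation null models, Elo dominance ratings, and a seeded
    synthetic-data generator for a closed island passerine population
    support end-to-end validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    glue,
    igraph,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
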