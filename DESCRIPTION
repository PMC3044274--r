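Package: psmreg
Title: Consistency-Based Re-Ranking of Peptide-Spectrum Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing of shotgun-proteomics search results by score
    regularization on a peptide affinity graph. Peptide-spectrum matches
    (PSMs) whose peptides co-occur in proteins are connected in a sparse
    similarity graph; new scores minimize a convex objective trading
    smoothness over the normalized graph Laplacian against fidelity to the
    search engine's initial scores, solved in closed form or by fixed-point
    iteration. Includes target-decoy ROC/AUC evaluation, a synthetic
    target-decoy search simulator for benchmarking, and command-line entry
    points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
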