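Package: slimq
Title: Query-Restricted De Novo Discovery of Short Linear Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo discovery of short linear motifs (SLiMs) in protein
    sequence datasets by over-representation statistics, with optional
    restriction of the motif search space to a query protein or region.
    Implements the three-cycle cumulative-binomial significance model over
    unrelated protein clusters (UPC), intrinsic-disorder masking, regex
    induction of motif definitions from aligned peptide instances, motif
    information-content comparison and rating of predictions, and a
    simulated protein-interaction benchmark generator with
    sensitivity and false-positive metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
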