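Package: hmmsieve
Title: Accelerated Profile Hidden Markov Model Search with a Word-Seeded Filter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profile hidden Markov model homology search for protein
    sequences with a four-stage acceleration filter (significant-word
    scan, ungapped diagonal extension, two-hit rule, windowed Viterbi
    gate), exact Viterbi and Forward scoring in bits, extreme-value
    E-value calibration, an iterative profile search that accretes
    homologs over a full database, and a shuffled-decoy benchmark
    toolkit (true positives versus errors per query, minimum error
    rate, bootstrap method comparison).  A synthetic protein-family
    generator makes every component testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
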