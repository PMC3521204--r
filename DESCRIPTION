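Package: dgrscan
Title: Detection and Analysis of Diversity-Generating Retroelements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects diversity-generating retroelements (DGRs) in bacterial
    DNA sequence by a sliding-window, wildcard-base repeat search anchored on
    reverse-transcriptase (RT) genes: template repeat (TR) / variable repeat
    (VR) pairs whose mismatches are restricted to TR adenines are found,
    maximally extended, filtered, assembled into cassettes and classified by
    architecture (including the inverted arrangement revealed by a
    generalized wildcard scan). Annotates RT proteins for the DGR-diagnostic
    motifs (the (I/V/L)GxxxSQ region-4 heptamer, the YxDD catalytic motif and
    the positively charged C-terminal patch), quantifies the adenine
    substitution spectrum with chi-square tests, reads and writes GenBank
    flat files, and generates annotated synthetic genomes with planted
    cassettes and decoys plus truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
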