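Package: mirtarscreen
Title: Computational Pipeline for Library-Based miRNA Targetome Reporter Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational stages of high-throughput 3'UTR
    reporter-library screens of miRNA-target interactions: tiling of full
    3'UTRs into reporter-sized overlapping fragments, canonical seed-site
    discovery (8mer, 7mer-m8, 7mer-A1, 6mer) by exact matching, RNA
    secondary-structure handling (dot-bracket parsing, a self-contained
    maximum-weight folding baseline, deterministic 2D layouts) with windowed
    paired-base fractions and a graph-layout coverage score of site
    accessibility, dual-luciferase reporter statistics (ratio-of-ratios
    normalization, Welch tests, validation calls, gene-level aggregation),
    bipartite miRNA-target network summaries, structure-repression
    correlation scans, and a fully deterministic synthetic-study generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
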