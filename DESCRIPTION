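Package: serascan
Title: Quantifying Serum-Derived RNA Contamination in Extracellular RNA
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and quantifying cross-species RNA
    contamination in cell-culture extracellular RNA sequencing, with a
    focus on fetal bovine serum (FBS) carry-over.  Implements a read
    quality gate based on the longest high-quality cycle span, competitive
    classification of reads against two reference genomes with a built-in
    seed-and-extend local aligner (plus an external SAM ingestion path), a
    species-specific-read contamination index with exact Mann-Whitney
    group comparisons, reads-per-million biotype composition analytics
    with Pearson-correlation hierarchical clustering, and qPCR analytics
    including geNorm reference-gene stability.  A synthetic-data module
    generates diverged genome pairs, labelled read mixtures at a known
    contamination fraction, biotype count tables and Cq tables, so the
    whole pipeline is testable against known ground truth without any
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
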