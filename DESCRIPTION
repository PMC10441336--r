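Package: scwgacnv
Title: Single-Cell Copy-Number Calling and Amplification QC for
    Whole-Genome-Amplified Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Read-depth copy-number analysis for shallow single-cell
    whole-genome sequencing of amplified nuclei (PicoPLEX, PTA, droplet
    MDA). Provides genomic binning with mappability-aware variable bins,
    fragment counting with mapping-quality filtering, GC correction,
    per-cell amplification-evenness metrics (neighbour-difference MAD,
    Lorenz/Gini, integer-copy-number confidence), PCA-based removal of
    read-depth variation shared across cells, permutation-based circular
    binary segmentation, integer copy-number assignment with data-derived
    gain/loss thresholds, multi-cell artifact filtering, chimeric
    read-pair classification, cohort summary statistics, and a synthetic
    cohort generator that emulates the noise characteristics of each
    amplification chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
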