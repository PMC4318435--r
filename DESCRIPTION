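Package: nucdyn
Title: Nucleosome Positioning and Salicylic-Acid-Induced Remodeling from
    Tiling-Array Enrichment Tracks
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Calls distinct and fuzzy nucleosome regions from replicate
    tiling-array log2 enrichment tracks across a sweep of stringency
    thresholds, detects base-resolution chromatin remodeling between a
    control and a salicylic-acid-treated condition, computes TSS-anchored
    occupancy and remodeling profiles stratified by expression class
    (SA-induced/repressed/constitutive/silent crossed with
    NPR1-dependent/independent), and scores cis-regulatory motif enrichment
    (W-box, TGA) with local-composition expected occurrence, binomial
    confidence intervals, and hexamer lift/observed-expected screens. A
    synthetic-data generator with planted ground truth makes the whole
    pipeline testable without microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    S4Vectors,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
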