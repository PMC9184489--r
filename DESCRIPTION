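Package: sedadiag
Title: Species Assignment from Target-Enriched Sedimentary Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns target-enriched sedimentary ancient DNA (sedaDNA) reads into
    species-level presence signals for pairs of closely related congeners
    sharing a collinear organelle genome. Implements diagnostic-site discovery
    between labelled chloroplast genome groups (anchored whole-genome
    alignment and fixed-difference calling), a k-mer lowest-common-ancestor
    read classifier with a confidence threshold, paired-end merging, seeded
    semi-global read mapping with per-site species assignment and
    deamination-aware masking, tandem satellite-repeat nucleotide-frequency
    profiling in wraparound phase, and terminal C-to-T / G-to-A damage
    profiling with an exponential decay fit for ancient-DNA authentication.
    A fully seeded synthetic-data generator produces truth-labelled reference
    panels, damaged read sets, PCR duplicates, repeat arrays and background
    reads for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
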