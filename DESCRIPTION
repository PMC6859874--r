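Package: dqcnv
Title: Dosage-Quotient Detection of Large Genomic Rearrangements from
    Amplicon Read Counts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects exon-level deletions and duplications (large genomic
    rearrangements) in targeted amplicon sequencing panels from per-amplicon
    read counts.  Implements the dosage-quotient (DQ) statistic in three
    normalization modes (intra-chip, panel-wide baseline, per-primer-pool
    baseline), per-amplicon mean +/- 2 SD thresholds with a consecutive-
    amplicon soft-evidence rule, a Viterbi copy-number HMM comparator with a
    configurable minimum segment length, sample triage for orthogonal MLPA
    confirmation, diagnostic validation metrics with Wilson score intervals,
    HGVS-style genomic deletion parsing with junction microhomology search,
    and a negative-binomial cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
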