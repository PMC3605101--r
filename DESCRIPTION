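Package: phenosam
Title: Quantitative SAM and Network Enrichment for Continuous-Phenotype Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relates bulk transcriptome profiles to continuous phenotypes
    (e.g. training-induced lean-mass gain, chronological age) using the
    quantitative variant of Significance Analysis of Microarrays (SAM) with a
    permutation-based false discovery rate, paired and two-class SAM variants,
    upstream-regulator inference (Fisher overlap p-value plus activation
    z-score against a signed regulator-target network), exhaustive positional
    gene enrichment with six pruning rules, cross-cohort replication of
    phenotype-correlated genes, and median/MAD-scaled principal component
    integration of phenotype and physiological variables. Includes a
    synthetic-cohort simulator with planted gene, regulator and locus signal
    so that every stage can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
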