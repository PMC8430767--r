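Package: grcr
Title: Positional Co-Expression Analysis of Gravity-Responsive Chromosomal Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects chromosomal regions in which differentially expressed
    genes cluster with a shared fold-change direction across independent
    expression comparisons.  Per-gene log2 fold changes are projected onto
    overlapping genomic windows as expression-weighted averages, traces from
    two comparisons are compared by Spearman correlation, and the observed
    coefficient is scored against a paired location-permutation null that
    preserves gene pairing while destroying co-location.  Companion analyses
    regress fold changes on chromatin structure (chromosome identity, arm
    ends, Alu density, replication timing, cytobands, TADs, LADs) with
    elastic-net models, pinpoint differential expression to chromosomes, and
    test differential Hi-C interaction bins for enrichment in the detected
    regions.  Synthetic-data generators reproduce the statistical structure
    the analysis assumes so every stage can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    glmnet,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
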