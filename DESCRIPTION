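Package: cinomics
Title: Chromosomal Instability Scoring and CIN-Stratified Multi-Omics Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying chromosomal instability (CIN) from
    segmented copy-number profiles via the weighted Genome Instability
    Index (wGII) and for downstream CIN-stratified analyses of matched
    organoid/tissue cohorts: organoid-tissue wGII concordance with
    outlier-robust regression, gene-level copy-state calls and
    alteration frequencies, differential protein analysis and
    RNA-protein integration, per-protein Pearson screening against
    wGII, hypergeometric over-representation of mitochondrial
    annotations, signature-based classification of external cohorts,
    and CIN-stratified prioritisation of gene dependencies and drug
    responses. A synthetic-cohort generator with recorded ground truth
    supports end-to-end testing of every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
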