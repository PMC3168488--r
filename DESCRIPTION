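Package: stratiq
Title: Stratified Transcriptomics Enrichment for QTL-Positional Candidate Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A stratified microarray analysis pipeline for prioritising
    tissue-specific candidate obesity genes in a divergent-line mouse model.
    Implements a pooled "snapshot" fold-change filter cascade across three
    white adipose depots with a non-adipose exclusion window, positional
    filtering against quantitative trait locus (QTL) confidence intervals,
    a replicated quantitative differential-expression stage using an
    empirical-Bayes moderated t-statistic with Benjamini-Hochberg false
    discovery rate control and diet-response classification, and
    hypergeometric over-representation analysis of candidate gene lists.
    Includes a synthetic expression-data generator with planted truth for
    end-to-end validation of the filter cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
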