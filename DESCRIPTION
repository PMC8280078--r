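Package: methrev
Title: Differential Methylation and Treatment Reversal Analysis for
    Bisulfite Sequencing Count Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for promoter-tile differential-methylation analysis of
    bisulfite capture sequencing experiments with a two-factor
    injury-by-treatment design. Reads Bismark coverage files into a
    SummarizedExperiment-derived container, applies per-sample depth
    filtering, blacklist exclusion and median-based coverage
    normalization, summarises CpG counts over 250 bp sliding windows,
    tests each tile for a group difference with a binomial
    logistic-regression likelihood-ratio test, adjusts p-values with a
    sliding-linear-model (SLIM) pi0 estimate, classifies
    injury-responsive tiles by whether a treatment contrast reverses
    their methylation change, aggregates tile effects per gene, and
    tests curated gene sets for hypergeometric over-representation.
    Includes a seeded generator of synthetic four-group bisulfite count
    data with planted, partially reversing injury effects for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    Sequencing, Coverage
RoxygenNote: 7.3.3
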