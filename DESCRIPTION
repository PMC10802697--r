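Package: cnvBurden
Title: Rare Copy-Number-Variant Burden Analysis for Case/Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for case/control association analysis of rare
    copy-number variants (CNVs) called from genotyping-array intensity data.
    Implements two-caller consensus calling, sample-level intensity and
    call-load quality control, a rare-CNV filter cascade (size, genomic-region
    masks, internal and external frequency, B-allele-frequency validation),
    covariate-adjusted global burden regressions with gene-set and constraint
    partitions, clumped gene- and breakpoint-based stratified exact
    Cochran-Mantel-Haenszel tests with permutation-based genomic-inflation
    control, a deletion-recurrence permutation test, and downstream carrier
    analyses (polygenic-score, comorbidity and treatment-response
    comparisons). Ships a synthetic-cohort generator with planted effects so
    every stage is testable end to end without access to genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
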