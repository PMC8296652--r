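Package: epistatus
Title: Metastable Epiallele Methylation Status Calling and Downstream
    Association Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing metastable epialleles such as the nc886
    (VTRNA2-1) differentially methylated region from methylation-array
    beta values. Identifies expression-associated and bimodally
    distributed CpGs (Hartigan's dip statistic plus a two-component
    mixture separation guard), classifies individuals into
    non-/intermediately-/hemi-/fully-methylated epiallele status groups
    by hierarchical clustering, and assesses longitudinal stability of
    the status. Downstream analyses cover delta-delta-Cq normalisation
    of qPCR expression with status-wise fold changes and rank tests,
    correlated-target hypergeometric gene-set enrichment (k/K reporting
    with Benjamini-Hochberg FDR), trapezoidal area-under-the-curve
    lifecourse trait estimates over age windows with status-association
    regression, and chi-squared tests of early-life categorical factors
    against status. A seeded synthetic-cohort generator with the full
    methylation/expression/trait/covariate structure supports testing
    every stage without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    mclust,
    fgsea,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: DNAMethylation, Epigenetics, Clustering, GeneSetEnrichment,
    GeneExpression, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'association-scan.R'
    'dip-test.R'
    'bimodality.R'
    'enrichment.R'
    'epistatus-package.R'
    'expression-assoc.R'
    'io.R'
    'lifecourse.R'
    'status-calling.R'
    'synthetic-cohort.R'
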