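Package: cistroSig
Title: Multi-Factor Cistrome Integration and Prognostic Gene Signatures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of transcription-factor ChIP-seq binding
    landscapes across tumor cohorts: consensus binding sites from per-sample
    peak sets, factor overlap and correlation structure, clinically
    stratified differential binding, proximal target-gene assignment, an
    elastic-net prognostic expression signature validated against a
    size-matched random-gene-set bootstrap null, survival stratification
    (Kaplan-Meier, log-rank, Cox), and a cross-cohort k-nearest-neighbor
    outcome classifier. Ships a synthetic cohort generator emulating
    multi-factor co-binding architecture, negative-binomial read counts,
    group-differential binding, prognostic target-gene expression and
    censored survival, so the whole pipeline is exercised end to end
    without access to patient data.
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
    GenomeInfoDb,
    SummarizedExperiment,
    DESeq2,
    glmnet,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ChIPSeq, Epigenetics, GeneExpression, Survival, Classification
Collate: 
    'AllClasses.R'
    'accessors.R'
    'genomic-intervals.R'
    'binding-matrix.R'
    'cistroSig-package.R'
    'differential.R'
    'expression.R'
    'io.R'
    'knn.R'
    'survival.R'
    'signature.R'
    'synthetic.R'
    'pipeline.R'
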