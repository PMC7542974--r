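Package: metaMiner
Title: Downstream Data Mining for Metabolomics Peak Tables
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scriptable downstream analysis for mass-spectrometry
    metabolomics peak tables: quality filtering (outlier replacement,
    minimum/KNN/QRILC imputation, total-intensity / internal-standard /
    QC-LOESS normalization, log and z-score transforms), compound
    annotation by exact mass or spectral similarity, reaction-pair ratio
    variable expansion, univariate testing with multiplicity correction,
    PCA and (O)PLS-DA with VIP scores and permutation validation, random
    forest / SVM / Boruta / joint marker screening, classical and
    generalized (metabolome-microbiome) correlation, pathway topology
    impact under seven centrality algorithms with hypergeometric
    metabolite-set enrichment, and supporting clustering, ROC, power and
    Venn utilities. Includes a synthetic-data generator so every analysis
    is testable end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mixOmics,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotate.R'
    'correlation.R'
    'extras.R'
    'metaMiner-package.R'
    'pathway.R'
    'preprocess.R'
    'ratios.R'
    'stats-latent.R'
    'screen.R'
    'stats-univariate.R'
    'synthetic.R'
    'tables-io.R'
    'workflows.R'
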