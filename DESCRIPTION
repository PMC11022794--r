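Package: consensusSNP
Title: Consensus SNP Selection for Categorical Traits via Gradient-Boosted
    Model Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies genomic variants predictive of a categorical
    phenotype (such as seed colour classes in a crop panel) by training an
    ensemble of multi-class extreme-gradient-boosted classifiers on random
    stratified train/test resamples of a 0/1/2-encoded genotype matrix,
    aggregating per-model gain importances into a consensus SNP set, and
    expanding that set with collinear (high linkage-disequilibrium) sites.
    Includes VCF import with hard site filters and 012 text round-tripping,
    a synthetic genotype-phenotype generator with population structure and
    planted causal variants, a univariate linear-mixed-model GWAS baseline
    with Wald tests against a centred relatedness matrix, PCA/LDA
    ordination with class-separation scoring and a population-structure
    confounding check, hierarchical-clustering genotype heatmaps, and
    SNP-to-gene annotation from GFF3 gene models with flanking regions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    xgboost,
    vcfR,
    pROC,
    cluster,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
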