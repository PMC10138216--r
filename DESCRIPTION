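Package: stimMII
Title: Clinical-Genetic Prediction of Mature Oocyte Yield After Ovarian
    Stimulation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the number of metaphase-II (MII) oocytes retrieved
    after controlled ovarian stimulation from clinical covariates and
    engineered genetic features. Implements the full feature-discovery
    pipeline: per-variant distribution tests (Kolmogorov-Smirnov and
    Mann-Whitney U), shadow-feature importance ranking, correspondence
    analysis of variant-by-outcome-group tables, self-organizing maps,
    haplotype-block detection (confidence intervals, four-gamete rule,
    solid spine of LD) with two-locus EM haplotype frequency estimation,
    and decision-tree reduction of haplotypes to binary features.
    Prediction uses gradient-boosted decision trees with grouped
    cross-validation, greedy forward selection of clinical features, an
    exhaustive genetic-feature combination search, and Shapley-value
    explanation of individual predictions. A synthetic-cohort generator
    reproduces the statistical structure of such studies (clinical
    marginals, block-structured linkage disequilibrium, planted effects)
    so the whole pipeline can be exercised and validated without access
    to patient data.
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
    VariantAnnotation,
    xgboost,
    ranger,
    rpart,
    cluster,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml
biocViews: StatisticalMethod, FeatureExtraction, Regression, SNP,
    LinkageDisequilibrium, MachineLearning
Config/testthat/edition: 3
RoxygenNote: 7.3.3
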