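Package: oncotriad
Title: Three-Layer Prioritization of Somatic Variants, Driver Genes and
    Targeted Drugs in a Personal Cancer Genome
Version: 0.1.0
Authors@R:
    person("Maintainer", "Oncotriad", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Interprets a single patient's somatic mutation profile in three
    layers. Layer one scores every variant for cancer-driving potential: point
    coding mutations through a calibrated radial-kernel support vector machine
    over eleven pathogenicity predictors, point non-coding mutations through a
    precomputed functional score lookup, and structural variants and indels
    through recurrent focal copy-number signal regions. Layer two aggregates
    per-gene score maxima, attaches a phenotype-driven prior, and converts the
    four features into a driver probability with a logistic model. Layer three
    classifies genes as tumor suppressors or oncogenes, expands to pathway
    neighbors, queries drug-gene interaction tables with role-specific term
    sets, and ranks candidate drugs by a multiplicative joint probability with
    regulatory tiers. Also provides a two-step binary dictionary index for
    fast interval queries on sorted key-coordinate text databases, a training
    and evaluation harness (cross-validated ROC with stratified bootstrap
    confidence intervals, backward feature selection), and synthetic fixture
    generators that emulate every required resource at miniature scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    VariantAnnotation,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
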