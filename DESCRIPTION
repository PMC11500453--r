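Package: microhdf
Title: Deep Forest Cascade Classification of Host Phenotypes from
    Microbiome Abundance Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary host phenotypes (case versus control) from
    taxon-by-sample relative-abundance profiles using a two-channel deep
    forest cascade. One channel learns from the raw abundance matrix, the
    other from phylogeny-derived feature matrices obtained by populating
    level-order and post-order traversal templates of a least-pruned
    taxonomy tree. Each cascade layer combines class-rebalancing random
    forest units (affinity-propagation clustering of the majority class
    on Bray-Curtis dissimilarity followed by stratified undersampling and
    minority bootstrapping) with dimensionality-reducing extremely
    randomized tree units (LDA-effect-score ranking plus sequential
    forward selection). Includes normalized impurity-based feature
    importance values for biomarker discovery, repeated stratified
    cross-validation and cross-study evaluation, and a synthetic
    generator for zero-inflated compositional microbiome data with
    planted differential taxa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    ranger,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
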