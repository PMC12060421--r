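Package: scDimorph
Title: Sex-Stratified Single-Cell Differential Expression and Network
    Perturbation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for sex-stratified single-cell
    transcriptomic analysis of transgenic-versus-wildtype designs:
    quality-control filtering, depth normalization and variable-gene
    selection, shared-nearest-neighbor clustering with silhouette-based
    resolution choice, marker-score cell-type annotation, per-gene
    Poisson-regression differential expression with sex-genotype and
    age-genotype interaction tests, classification of genes into
    sex-neutral, sex-specific and sex-dimorphic categories,
    over-representation analysis against gene-set collections,
    condition-specific refinement of prior-knowledge regulatory networks
    by genetic-algorithm optimization of sign consistency, network
    perturbation scoring of candidate regulators, and Y-maze spontaneous
    alternation scoring with two-way ANOVA. A synthetic-data module
    generates count matrices, prior networks and arm-entry sequences with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    cluster,
    car,
    emmeans,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
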