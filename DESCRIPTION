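Package: droughtscreen
Title: Multi-Stage Drought-Tolerance Screening for Wheat Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for classifying crop genotypes by drought
    tolerance from multi-environment split-plot trials. Provides combined
    split-plot analysis of variance, ANOVA-based variance components and
    genetic parameters (broad-sense heritability, genotypic and phenotypic
    coefficients of variation, genetic advance and genetic gain),
    multicollinearity screening with iterative trait exclusion,
    correlation-matrix principal component analysis, forward stepwise
    regression of grain yield with path-coefficient decomposition of
    trait-yield correlations, a min-max membership index that converts
    stress/control trait ratios into a five-rank tolerance classification,
    and multivariate validation of the resulting groups (hierarchical
    clustering, principal coordinates analysis, Mantel test, canonical
    discriminant analysis, Box's M with quadratic discriminant
    classification, and MANOVA with least-squares means). A synthetic trial
    generator with known variance components and genetic correlation
    structure supports benchmarking of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
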