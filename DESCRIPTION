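Package: fcgnet
Title: Sex-Factor Dissection of Mood-Gene Expression and Co-Expression
    Networks in Four Core Genotypes Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for dissecting how sex chromosome
    complement, developmental gonadal sex, and adult circulating
    testosterone shape frontal-cortex expression of mood-related genes in
    the Four Core Genotypes mouse model. Covers qPCR delta-Ct
    quantification against two reference genes, per-gene three-way
    factorial ANOVA with Tukey follow-ups and Benjamini-Hochberg control
    within gene categories, composite behavioral emotionality Z-scores,
    stratified gene-behavior Pearson correlation, male/female phenotype
    expression-ratio matrices, and |r|^3-weighted gene co-expression
    networks whose global properties (density, weighted clustering
    coefficient, degree assortativity) are compared between groups by
    label-permutation testing. A seeded synthetic-data generator with
    planted factor effects and group-specific co-expression modules makes
    every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
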