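Package: groupbv
Title: Genetic Evaluation from Group Records with Varying Group Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based estimation of variance components and prediction of
    breeding values when phenotypes are only observed as group totals (for
    example pen-level feed intake in pigs). Individual-level animal models with
    litter and pen environmental effects are aggregated to the group level
    through an indicator transformation, giving a linear mixed model with
    heterogeneous residual weights equal to group size. Variance components are
    estimated by average-information REML with exact sparse traces and breeding
    values by BLUP from Henderson's mixed-model equations. Includes closed-form
    group-level variance decompositions, identifiability diagnostics for
    confounded pen and residual (or litter and pen) effects, a stochastic pig
    population simulator with litter and pen structures and random attrition,
    and a replicate experiment runner for accuracy and bias of predicted
    breeding values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
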