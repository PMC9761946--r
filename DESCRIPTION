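Package: bnmiss
Title: Bayesian Network Structure Learning from Incomplete Categorical Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how missing data handling affects discrete
    Bayesian network structure learning. Generates random parameterised
    networks, samples categorical data, introduces missing values under
    MCAR, MAR and MNAR via multivariate amputation, and learns structures
    with complete-case analysis, chained-equation imputation (polytomous
    logistic models) or hard-assignment structural EM, all on top of a
    BDe/BDs/BIC scoring engine with tabu search. Provides skeleton
    precision/recall and Hamming-distance evaluation with ANOVA, Bonferroni
    and Tukey HSD aggregation, a factorial experiment runner, and a survey
    analysis stage with repeated-seed structural EM, arc-strength consensus
    networks and edge-betweenness community detection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
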