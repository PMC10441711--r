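Package: mmnet
Title: Multimorbidity Networks and Hospitalisation in Ageing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how chronic-disease multimorbidity relates to
    hospitalisation in population-based ageing cohorts. Provides a synthetic
    cohort generator with a known Ising ground truth emulating the structure of
    large ageing-survey data (19 self-reported morbidities, survey weights,
    missing-at-random incompleteness); inverse-probability weighting for
    complete-case analysis; survey-weighted Poisson prevalence-ratio and
    robust linear models for hospitalisation, readmission, and length of stay
    under two multimorbidity definitions; Ising disease-network estimation by
    nodewise L1-penalised logistic regression with extended-BIC model selection
    (eLASSO); Walktrap community detection with bootstrap stability; node
    predictability and centrality (strength, closeness, betweenness,
    participation coefficient); and nonparametric edge bootstraps, difference
    tests, and case-dropping correlation-stability coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    sandwich,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
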