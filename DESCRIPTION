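Package: aeropower
Title: Predicting Wingate Anaerobic Power Outputs from Incremental
    Cardiopulmonary Exercise Test Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the mechanical power outputs of the 30-second
    Wingate anaerobic test (peak power, mean power, fatigue index) from
    breath-by-breath maximal incremental cardiopulmonary exercise test (CPET)
    recordings.  Provides a canonical registry of 51 aerobic features (12
    directly measured, 39 calculated), V-slope detection of the ventilatory
    anaerobic threshold by exhaustive two-segment least squares, a greedy
    forward feature-selection regression with an adjusted R-squared stopping
    rule, stability voting over repeated random splits, cross-validated
    evaluation (Spearman correlation, RMSE, percent error), and clustering of
    the feature correlation network by Newman leading-eigenvector modularity
    maximization.  A synthetic cohort generator with planted linear signal
    structure makes every stage testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
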