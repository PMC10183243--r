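Package: distressnet
Title: Regularized Partial-Correlation Networks of Stress and Mental-Distress Symptoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates Gaussian graphical models of ordinal symptom
    questionnaire data (such as the 21-item Depression Anxiety Stress
    Scales) via the nonparanormal transformation and EBIC-selected
    graphical LASSO, and describes the resulting network with strength
    centrality, community-aware bridge statistics, nodewise
    predictability, and case-dropping bootstrap stability
    (correlation-stability coefficients). Includes a latent-Gaussian
    threshold simulator for generating questionnaire-like data with
    known network structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
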