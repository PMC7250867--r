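Package: postbias
Title: Post-Decisional Evidence Accumulation and Confidence-Induced Confirmation Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how confidence shapes the accumulation of
    post-decisional evidence in two-stage perceptual decisions. Provides a
    synthetic-data generator for factorial random-dot-motion sessions with
    staircase-calibrated coherences and sensor-space epochs carrying a
    decodable decision signal; a Wiener first-passage-time core with a
    ten-model hierarchical Bayesian regression family over starting point,
    drift rate and boundary separation, fitted by adaptive MCMC and compared
    by DIC; a classifier-derived neural decision-variable pipeline (sliding
    window features, linear support-vector decoders, trial-wise slope and
    intercept extraction, sensor contribution maps, temporal generalization);
    and group-level statistics including hierarchical regression, cluster-based
    sign-flip permutation tests and multilevel bootstrap mediation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    e1071,
    signal,
    lme4,
    yaml,
    jsonlite,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
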