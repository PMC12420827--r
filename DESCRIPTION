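Package: hydrodiv
Title: Hydraulic-Trait Diversity and Simulated Forest Drought Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, individual- and trait-based forest stand simulator
    with explicit plant hydraulics (xylem vulnerability, rooting profiles,
    leaf phenology), a stochastic monthly-to-daily weather generator driven by
    anomaly-scaled climatologies, orchestration of through-fall-exclusion
    drought and diversity-manipulation experiments, functional-trait diversity
    metrics (Gower dissimilarity with asymmetric binaries, Rao's quadratic
    entropy, community-weighted means, trait-space PCA), and the inference
    layer linking diversity to drought resistance: a heteroscedastic Bayesian
    regression with Bayes-factor model comparison and a linear mixed-effects
    model with AIC-guided interaction pruning and prediction grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    lme4,
    cluster,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
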