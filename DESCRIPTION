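Package: timweb
Title: Structured Trophic Interaction Modifications and Food-Web Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how structured trophic interaction
    modifications (TIMs) — higher-order interactions in which a third species
    alters the strength of a consumer-resource link — reshape food-web structure,
    local stability, and feasibility. Generates niche-model food webs
    parameterised with correlated bivariate-Gaussian interaction strengths,
    samples TIMs under seven distribution models, collapses them into
    non-trophic-effect matrices, and measures structural metrics, leading
    eigenvalues, and feasibility-domain size (orthant probabilities). Also
    implements generalized Lotka-Volterra dynamics with 3- and 4-way interaction
    tensors and the critical-interaction-strength search used to probe
    diversity-stability relationships under higher-order interactions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    mvtnorm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
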