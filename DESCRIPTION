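Package: airineq
Title: County-Level Air Pollution Exposure and Spatial Inequality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying population-weighted air pollution exposure
    (APE) and its within-county spatial inequality (spatial Gini index, SGI)
    from gridded pollutant and population surfaces, together with the urban-form
    and socio-economic indicators commonly used to explain them: residential
    income segregation (dissimilarity index), the urban centrality index, POI /
    road / population densities, and a land-conversion pressure index. Driver
    analysis covers log-transformed bivariate OLS, standardized PCA, and
    regularized partial-correlation networks selected by the extended Bayesian
    information criterion over a graphical-lasso path, with bootstrap stability
    assessment. A fully synthetic province generator with planted statistical
    structure (spatially autocorrelated concentration fields, heavy-tailed
    population, controllable segregation and centrality, planted covariate
    effects) makes the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp, RcppArmadillo
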