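Package: ordgmm
Title: Gaussian Mixture Recovery from Ordinal Thresholded Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo study of how thresholding continuous multivariate
    data into ordinal categories degrades Gaussian-mixture recovery by the
    EM algorithm with BIC model selection. Constructs data-generating
    mixtures whose components are pairwise equidistant in Kullback-Leibler
    divergence, maps samples onto midpoint-labeled ordinal scales between
    the 0.5% and 99.5% quantiles, fits spherical and unconstrained Gaussian
    mixtures over a sequence of component counts, and scores recovery of
    the number of components and of the component parameters after optimal
    permutation matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
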