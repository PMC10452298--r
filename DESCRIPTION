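Package: phylocount
Title: Phylogenetic Poisson and Negative Binomial Regression for Count Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression models for count-valued traits measured across related
    species. Fits independent Poisson and negative binomial (NB2) generalized
    linear models, and their phylogenetic counterparts via generalized
    estimating equations (GEE) in which the working covariance embeds the
    shared-branch-length matrix C derived from a phylogenetic tree. Includes
    Gaussian-copula (NORTA) simulators for phylogenetically correlated counts,
    Brownian-motion covariate simulation, a replicated simulation-study driver,
    parametric bootstrap inference, and AICc/Akaike-weight model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
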