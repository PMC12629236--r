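Package: tcvs
Title: Tree-Guided Compositional Variable Selection for Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies outcome-associated taxa in compositional microbiome
    data by combining a sum-to-zero-constrained sparse group lasso, whose
    groups come from the taxonomic tree, with Gaussian model-X knockoff
    copies of the centered log-ratio (CLR) covariates. Provides the
    constrained solver (ADMM with an exact hierarchical proximal operator),
    knockoff construction, the knockoff statistic and data-dependent
    selection threshold, BIC tuning, ablation variants (tree-only,
    knockoff-only, plain constrained lasso), a Dirichlet-Multinomial
    simulation engine with benchmark and effect-size-sweep protocols, and a
    bootstrap resampling evaluation with constrained OLS refitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
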