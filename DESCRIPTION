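Package: srmtie
Title: Multilevel Probit Social Relations Model for Directed Binary Ties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the multilevel probit Social Relations Model (SRM) to
    directed binary ties observed among members of multiple bounded groups
    (round-robin designs), using Markov chain Monte Carlo with latent-variable
    augmentation. Decomposes latent tie variance into group, actor, partner,
    and dyadic components (variance partition coefficients), estimates
    generalized and dyadic reciprocity correlations, constructs actor-,
    partner-, and dyad-level covariates including multiplicative homophily
    terms, and produces posterior prediction grids. Includes a generative
    simulator of multi-group directed networks for testing and parameter
    recovery, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
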