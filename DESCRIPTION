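Package: krillphase
Title: Phase-Randomised Integrated Stock Assessment for Antarctic Krill
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Length-based, age-structured integrated stock assessment for
    Antarctic krill (Euphausia superba) fitted by penalized maximum
    likelihood to acoustic and trawl survey biomass indices, survey and
    fishery length compositions, and fishery catches. Supports configurable
    estimation of up to 118 parameters in named configurations,
    phase-randomized replicate fitting with an invertible-Hessian
    convergence gate, asymptotic (delta-method) and Metropolis-Hastings
    MCMC uncertainty with convergence diagnostics, AIC/BIC model
    comparison, operating-/estimating-model self- and cross-tests, and a
    synthetic data generator emulating the CCAMLR Subarea 48.1 survey and
    fishery design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    coda,
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
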