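Package: prepmarkov
Title: Mixed-Effects Markov Modelling of Daily PrEP Adherence from Electronic Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing daily medication adherence recorded by electronic
    monitoring (MEMS) caps as a two-state, first-order, discrete-time Markov chain
    with subject-level random effects. Reads event logs into daily binary dose
    states, builds transition records, fits logit-parameterized Bernoulli and
    Markov mixed-effects models by Laplace-approximated (or adaptive Gauss-Hermite)
    maximum likelihood, screens and backward-eliminates covariates on odds-ratio
    confidence intervals, computes non-therapeutic time (NTT) diagnostics and
    replicate transition-count predictive checks, simulates synthetic cohorts with
    known generating parameters, and links adherence chains to plasma
    concentration profiles through closed-form compartmental pharmacokinetic
    superposition.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
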