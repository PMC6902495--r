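Package: augseq
Title: Adaptive Group-Sequential Trials with Early-Endpoint Augmented
    Interim Analyses
Version: 0.1.0
Authors@R:
    person("Warwick", "Trials Methods", email = "methods@example.org",
           role = c("aut", "cre"))
Description: Design, monitoring and simulation of two-arm group-sequential
    clinical trials in which repeated early (short-term) measurements of the
    primary outcome augment the long-term outcome at interim analyses. Provides
    the augmented treatment-effect estimator and its variance for correlated
    multivariate-normal endpoints, information-based look scheduling,
    error-spending futility and efficacy boundaries computed by stagewise
    numerical integration, interim decision rules with an overrunning final
    analysis, and trial simulation (multicentre Poisson recruitment, outcome
    generation, sequential nuisance estimation) to estimate operating
    characteristics such as stopping probabilities, power and expected sample
    size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
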