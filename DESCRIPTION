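Package: adlirt
Title: Longitudinal Graded-Response Modelling of ADL Disability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian longitudinal item response theory for six-item Katz
    activities-of-daily-living panels. Implements the Samejima graded
    response model with a subject-level linear latent-disability trajectory,
    Metropolis-within-Gibbs MCMC estimation of item discriminations and
    ordered difficulty thresholds, extraction of the ADL-loss hierarchy and
    partial-to-total threshold gaps, mixed-effects modelling of disability
    over the years before death, and a mortality-truncated panel simulator
    for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
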