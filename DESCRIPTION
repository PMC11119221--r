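Package: mlmexplore
Title: Exhaustive Data-Driven Exploration of Linear Mixed-Effects Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates every admissible candidate linear mixed-effects model
    from a user-specified full model (free fixed effects, forced covariates,
    a random intercept and candidate random slopes over a single grouping
    factor), fits each candidate by maximum likelihood, and ranks the
    candidates by AIC, BIC or log-likelihood. Nominations can be
    cross-checked with Bayes-factor arithmetic via the Schwarz (BIC)
    approximation and Kass-Raftery evidence categories. Includes a synthetic
    multi-group data generator emulating multi-country survey designs, a
    deterministic parallel exploration driver, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
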