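Package: coldtreat
Title: Time-Mortality Modelling and Efficacy Arithmetic for Cold
    Disinfestation Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for phytosanitary cold-treatment
    efficacy studies on fruit-infesting insects: beta-binomial
    time-mortality models fitted by maximum likelihood (with optional
    replicate-level random intercepts integrated by Laplace
    approximation), lethal-time estimation at arbitrary mortality levels
    including the probit-9 quarantine standard (99.9968%) with Fieller
    confidence intervals, large-scale-trial efficacy arithmetic
    (treated-number extrapolation from control counts and zero-survivor
    confidence bounds), mortality bookkeeping from pupal counts,
    temperature-profile quality assurance for cold stores, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB
Config/testthat/edition: 3
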