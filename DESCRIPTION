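Package: egmoss
Title: Stress-Strength Reliability Inference for Exponentiated
    Generalized Marshall-Olkin Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distribution functions, random generation and full
    stress-strength reliability inference for the exponentiated
    generalized Marshall-Olkin (EGMO-G) family with Weibull and
    exponential baselines. Provides joint and plug-in maximum
    likelihood estimation of R = P(Y < X) with delta-method and
    percentile-bootstrap confidence intervals, Bayesian estimation
    under independent gamma priors (Gibbs-within-Metropolis-Hastings
    sampling, an F-distribution credible interval and a closed-form
    posterior mean via the Gauss hypergeometric function), a Monte
    Carlo study driver, and goodness-of-fit comparison of the family
    against its nested sub-models (log-likelihood, AIC, BIC,
    Kolmogorov-Smirnov). Ships the carbon-fibre strength and COVID-19
    case-rate datasets used in the applications.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
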