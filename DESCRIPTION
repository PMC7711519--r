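Package: phldss
Title: Stress-Strength Reliability Estimation for the Poisson Half-Logistic Distribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the stress-strength reliability R = P(Y < X) when the
    strength X and the stress Y are independent Poisson half-logistic random
    variables.  Provides the distribution functions (density, distribution,
    quantile, random generation, raw moments), maximum-likelihood fitting of the
    general four-parameter and common-scale three-parameter models, delta-method
    asymptotic confidence intervals built from observed or expected information,
    nonparametric percentile and studentized bootstrap intervals, Bayesian
    estimation under squared-error, absolute-error, LINEX, general-entropy and
    maximum-a-posteriori criteria via Metropolis-Hastings-within-Gibbs sampling
    with highest-posterior-density credible intervals, and a seeded Monte Carlo
    harness reporting bias, mean squared error, interval length and coverage.
    Ships the carbon-fibre strength and bank waiting-time datasets used in the
    worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
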