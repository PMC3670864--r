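Package: sprgame
Title: Statistical Population Reconstruction for Small Game Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical population reconstruction (SPR) from two-age-class
    (young-of-the-year / adult) age-at-harvest data. Implements conditional
    cohort likelihoods with temporal random effects on survival and harvest
    vulnerability, marginal maximum likelihood via the Laplace approximation,
    second-stage Horvitz-Thompson abundance estimation, a stochastic
    Leslie-matrix population simulator, a Monte Carlo performance harness,
    and a two-season wild-turkey reconstruction model with known removals.
    Ships the East Ozarks (Missouri, USA) male wild turkey age-at-harvest
    dataset as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    TMB
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
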