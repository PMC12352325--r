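Package: pasindex
Title: Fuzzy-Hybrid TOPSIS Physical Activity Index and Ordered Probit Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a Physical Activity Synthetic Indicator (PASI) from nine
    ordinal survey items by converting responses to triangular fuzzy numbers
    on a common [0,100] universe of discourse and ranking respondents or
    population segments by their TOPSIS closeness to positive and negative
    ideal solutions. The PASI distribution is discretized into quintiles and
    modelled with a hand-coded maximum-likelihood ordered probit whose
    categorical covariates use the Daly (weighted sum-to-zero) normalization,
    so every coefficient reads as a deviation from the average citizen.
    Includes marginal effects for the most-sedentary outcome, a synthetic
    survey-microdata generator with known ground truth, and an end-to-end
    pipeline that writes ideal-solution, segment-PASI and marginal-effects
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
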