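Package: sexmort
Title: Bayesian Hierarchical Estimation of Sex Ratios of Mortality at
    Ages 0-24
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the sex ratio of mortality (male to female
    mortality rate) for ages 0-4, 5-14, and 15-24 years from
    multi-source observation databases (vital registration, survey birth
    and sibling histories, census household deaths) using a Bayesian
    hierarchical time-series model.  The country-year sex ratio is the
    product of a global expected-ratio curve, a function of total
    mortality, and a country-specific multiplier that fluctuates around
    one with AR(1) persistence; the observation model separates sampling
    error from source-type-specific non-sampling error.  Includes a
    synthetic-data generator with known ground truth, posterior
    trajectory sampling, derivation of sex-specific mortality, excess
    female mortality and outlier flags, regional aggregation of
    sex-specific deaths, and out-of-sample validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
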