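Package: creeleffort
Title: Weather, Tropical Cyclone, and Pandemic Effects on Weekly
    Recreational Fishing Effort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyze weekly creel-survey estimates of
    recreational fishing effort in a two-region subtropical coastal system.
    Provides a synthetic-data generator with known ground truth (seasonal
    weather processes, marine-advisory counts, a tropical-cyclone catalog,
    and a pandemic-year effort anomaly), data-preparation utilities
    (effort-weighted weekly covariate aggregation, warning-week
    realignment, exclusion filtering, standardization), a Bayesian
    hierarchical varying-slopes regression of log effort on weather with
    monthly random effects and a second-level month trend on the
    temperature coefficient, a hierarchical post-landfall effort-recovery
    model with a storm-severity level-2 regression, a pandemic-year
    percent-of-normal comparison, and MCMC convergence diagnostics.
    Models are fit with JAGS via 'rjags'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    rjags,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
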