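Package: msipm
Title: Multi-Species Integrated Population Models for a Seabird Breeding Community
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and fits multi-species integrated population models (msIPMs)
    for a community of colonially breeding seabirds: binomial likelihoods for
    breeding success and non-breeding, Cormack-Jolly-Seber mark-resight models
    for adults with one-year trap dependence, a two-state mark-resight-recovery
    likelihood for birds banded as chicks (with permanent emigration, band loss
    and a time trend in dead-recovery reporting), binomial state-space
    population dynamics with a normal observation model, and a hierarchical
    random-effects layer that partitions between-year variance in productivity
    and adult survival into community-wide (synchronous) and species-specific
    (asynchronous) components. Includes a synthetic-data generator that is the
    exact generative dual of the fitted likelihoods, Bayesian fitting by MCMC
    through JAGS, convergence diagnostics, and a simulate/fit/summarize/recover
    pipeline for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
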