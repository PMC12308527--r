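Package: odload
Title: Forward-Time Simulation of Inbreeding Load from Dominant and
    Overdominant Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Individual-based Wright-Fisher simulation of partially
    self-fertilizing and bottlenecked diploid populations carrying
    partially recessive deleterious, lethal, overdominant and neutral
    mutations under an infinite-sites model. Computes inbreeding load (B,
    in lethal equivalents), expressed load (L), maximum attainable
    fitness (W_max), inbreeding depression of selfed progeny (delta) and
    its marker-based rate estimate (delta*), together with closed-form
    and exact single-locus Markov-chain references used to validate the
    engine. Supports the classical (1 - s_o, 1, 1 - s_o) and alternative
    (1, 1 + s_o, 1) overdominance fitness schemes for viability or
    fecundity, free recombination or a genetic map, and replicated
    selfing-sweep and bottleneck-line experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'analytic-oracles.R'
    'load-metrics.R'
    'mutation-model.R'
    'population-engine.R'
    'experiments.R'
    'io.R'
    'odload-package.R'
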