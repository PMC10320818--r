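Package: bmsampler
Title: Mutation Sampler Models of Probabilistic Causal Judgment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generative process models of probabilistic causal judgment over
    three-variable causal Bayesian networks. Implements the Mutation Sampler
    (prototype-initialized Metropolis-Hastings chains over network states with
    relative-frequency judgments) and its Bayesian extension (symmetric
    Beta(beta, beta) pseudo-count judgments), exact normative inference for
    chain, common-cause and noisy-OR common-effect structures, simulation of
    full response distributions on the 0-100 percent scale, grid-search model
    fitting via kernel-density synthetic likelihood, BIC model comparison,
    parameter-recovery studies, and distributional response analyses (Gini
    mean difference, accuracy, conservatism, symmetry-collapsed inference
    groups).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
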