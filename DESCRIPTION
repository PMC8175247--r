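Package: reactnorm
Title: Reaction Norms, Multi-Laboratory Simulation and Replication Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying reproducibility of animal experiments through
    the lens of reaction norms. Composes genotype-specific reaction norms with
    environment distributions to obtain the induced distribution of expected
    trait values, aggregates many small-effect environmental factors into
    their Gaussian limit, simulates multi-laboratory experiments with a
    dominating environmental factor, genotype-by-environment interaction and
    within-lab noise, assesses replication success under naive, shifted
    confidence-interval and tail-product criteria, and performs random-lab-model
    inference with a G-by-E penalized standard error, including a
    method-of-moments estimator of the G-by-E variance component and coverage
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
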