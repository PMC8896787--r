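Package: rattention
Title: Rational Inattention Models of Orientation Discrimination Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling two-alternative forced-choice (2AFC)
    orientation discrimination under limited processing resources. Implements
    a Bayesian observer with costly, adaptively allocated sensory precision
    (von Mises encoding noise, Bayesian least-squares decoding, late decision
    noise), endogenous optimization of the resource gain function per
    stimulus-reward environment, descriptive probit choice models with lapse
    and history terms, a confidence-gated distributional reinforcement
    learning allocator with divisive normalization, a Poisson population-code
    implementation, psychometric and multidimensional-scaling analyses,
    maximum-likelihood fitting with AIC/BIC model comparison, and a synthetic
    task and simulated-subject generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
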