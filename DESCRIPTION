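Package: mipsage
Title: Psychophysical Modelling of Motion-Position Integration Across Age Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-alternative forced-choice (2AFC) position
    and speed judgements of motion-induced position shift (MIPS) stimuli.
    Provides a synthetic-observer simulator for standard MIPS designs,
    single-subject maximum-likelihood and hierarchical Bayesian fitting of
    cumulative-Gaussian psychometric functions with a lapse rate, a
    three-line piecewise model of the MIPS time course with an initial-rate
    estimator, an optimal sequential-integrator model that decomposes
    response variability into sensory and propagation noise, and the
    split-plot ANOVA, Welch, Tukey and correlation machinery used to compare
    young and older observers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
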