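Package: tvatoj
Title: Hierarchical Bayesian TVA Analysis of Temporal-Order Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models temporal-order judgments (TOJ) as a capacity-limited
    independent race between two stimuli, following Bundesen's Theory of
    Visual Attention (TVA). Provides the closed-form two-parameter TOJ
    psychometric function in overall processing capacity C (Hz) and
    salience kappa, a Monte-Carlo race oracle, a generator for display-
    onset-asynchrony (DOA) by stimulus-onset-asynchrony (SOA) experiments
    with hierarchical participant structure, hierarchical Bayesian
    estimation of C and kappa per DOA condition (via JAGS), model-variant
    comparison by Pareto-smoothed importance-sampling leave-one-out
    cross-validation (looIC), and region-of-practical-equivalence (ROPE)
    tests on posterior standardized effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
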