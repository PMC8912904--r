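Package: metasl
Title: Meta-Control of Individual and Social Learning in Non-Stationary Bandits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation toolkit for studying the arbitration between
    individual learning and social learning strategies (success-based and
    conformist copying) in non-stationary multi-armed bandit environments.
    Provides configurable bandit environments with abrupt, random and gradual
    reward changes; epsilon-greedy individual learners and social learning
    action rules; the optimum distribution prediction uncertainty (ODPU)
    statistic based on order statistics of Gaussian maxima; binary context
    encoding (environment change, conformity, uncertainty); a family of
    meta-control strategies (rule-based, evolved discrete policies, a small
    feedforward network trained by neuroevolution, and value-based
    controllers); a replicator-mutator ordinary differential equation model;
    agent-based evolutionary simulations with fitness-proportionate selection
    and age tracking; and experiment runners with Wilcoxon rank-sum and
    Friedman/Nemenyi rank statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
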