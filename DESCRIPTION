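Package: volatilearn
Title: Volatility-Adaptive Reward Learning: Task Simulation and Model Fitting
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how decision makers adapt their learning rate
    to the volatility of a probabilistic reward environment. Simulates
    two-armed "pirate chest" bandit schedules with stable and volatile phases,
    runs an ideal Bayesian observer that jointly tracks reward probability,
    volatility and volatility drift on a discretized grid, generates synthetic
    choice data from delta-rule and degenerate strategy agents, compares
    candidate strategies per subject with penalized logistic regression,
    estimates Rescorla-Wagner learning rates by windowed maximum likelihood,
    quantifies post-reversal adaptation with running-average regression
    slopes, and reproduces the standard group-level statistics (mixed ANOVA,
    repeated contrasts, t-tests, confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
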