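Package: revlearn
Title: Simulation and Computational Modelling of Probabilistic Reversal
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying flexible decision-making in probabilistic
    Go/NoGo reversal-learning tasks. Generates the blocked task design with
    mid-block contingency reversals, simulates four behavioural agents
    (random responding, noisy win-stay-lose-switch, Rescorla-Wagner, and a
    two-level Hierarchical Gaussian Filter), fits the learning models to
    choice data by maximum a posteriori estimation with Laplace log-model
    evidence, performs random-effects Bayesian model selection, computes
    model-independent behavioural summaries such as p(staying) and
    phase-wise accuracy, and runs a cross-phase representational similarity
    analysis with stimulus- and outcome-selective model RDMs and
    permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
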