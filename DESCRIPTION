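Package: offlinereg
Title: Discount Regularization and State-Action-Specific Regularization
    for Offline Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regularized certainty-equivalence planning from sparse
    batch data. Implements discount regularization and its equivalent forms (a
    weighted-average transition matrix and a Dirichlet prior whose magnitude
    scales with the per-state-action transition count), closed-form
    state-action-specific shrinkage parameters that minimize the transition-row
    mean squared error, fitted Q-iteration with a weighted-average Bellman
    update and per-state-action regularization, a kernel-regression
    (Nadaraya-Watson) extension to one-dimensional continuous state spaces with
    regularized fitted value iteration, seedable benchmark environments
    (10-state random chain, River Swim, 4x4 GridWorld, continuous River Swim),
    and a replicated sweep harness that scores learned policies by their value
    loss against the true optimal policy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
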