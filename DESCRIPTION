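Package: deepdtr
Title: Deep Q-Learning for Dynamic Treatment Regimes from Registry Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates optimal dynamic treatment regimes from registry-style
    longitudinal observational data by offline deep Q-learning. Provides a
    registry data model for post-transplant trajectories (graft-versus-host
    disease states, drug-combination actions, quality-of-life rewards),
    supervised expert-action screening networks, an offline deep Q-network
    trained by experience replay with a softly tracked target network, and
    two off-policy evaluation protocols (matched-trajectory reward with
    bootstrap confidence intervals, and counterfactual value via a learned
    reward model). A synthetic registry simulator with an exact
    dynamic-programming oracle makes every stage of the pipeline testable
    without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
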