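Package: mazerl
Title: Reinforcement-Learning Agents and Trajectory Analytics for Dynamic-Barrier Maze Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing goal-directed navigation behaviour with tabular
    reinforcement-learning agents in a reconfigurable gridworld with movable
    barriers. Provides model-free Q(lambda), successor-representation, and
    model-based planning agents with optimal-policy initialization;
    forced-trajectory likelihood computation and bounded maximum-likelihood
    parameter estimation with model comparison; per-individual agent simulation
    under a decaying epsilon-greedy policy; trajectory analytics (occupancy
    maps, deviation from optimal paths, diffusivity features, Mahalanobis
    dissimilarity, minimum path-distance similarity, difficulty rankings); and
    a synthetic-data generator producing barrier layouts with tortuosity-graded
    start locations plus surrogate subjects from ground-truth agents for
    parameter-recovery and model-identification studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
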