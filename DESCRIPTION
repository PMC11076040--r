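Package: collabhunt
Title: Chase-and-Escape Simulation and Independent Deep Q-Learning for
    Collaborative Hunting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional continuous-space, discrete-time predator-prey
    chase-and-escape world together with the learning and analysis machinery
    used to study the emergence of collaborative hunting: independent
    per-agent dueling double deep Q-networks with prioritized experience
    replay, fully specified rule-based chaser/blocker predator policies,
    behavioral cloning of those policies into one-hidden-layer networks, and
    the behavioral statistics used to characterize role division (success
    proportions against the independence prediction, occupancy heat maps and
    their correlations, action concordance, circular correlation of action
    directions, and two-dimensional embeddings of network hidden layers).
    The simulation physics, network arithmetic and replay sampling are
    implemented both as plain R reference functions and as a fused C++ core
    for training-scale workloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
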