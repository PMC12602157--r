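Package: beeflow
Title: Agent-Based Simulation of Bee Foraging and Pollen Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatially explicit, discrete-time agent-based simulator of
    central-place foraging bees whose movement decisions arise from
    reinforcement learning of flight vectors (Q-values over plant-to-plant
    transitions, softmax action selection, short-term working memory),
    coupled to a geometric pollen-carryover model that records every
    donor-to-recipient pollen transfer. Provides the foraging-behaviour
    metrics (visits per bout, nectar intake rate, route similarity index,
    local intensity of competition, visitors per plant) and
    pollination-pattern metrics (pollen-weighted median mating distance,
    self-pollination rate, mate diversity, and normalized weighted
    bipartite network modularity via label-propagation optimization),
    plus seeded parameter-sweep experiment orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
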