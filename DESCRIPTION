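Package: spinesim
Title: Simulated Dendritic Spine Loss in a Deep Reinforcement Learning Agent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational model of major depressive disorder built on deep
    temporal-difference (TD) learning. A goal-seeking agent in a partially
    observable gridworld learns action values with a small tanh network; applying
    weight decay to the network's connection weights simulates the loss of
    dendritic spines observed in depression. The package implements the gridworld,
    the TD value-learning core, alternative depression model variants (reduced
    reward-prediction-error signaling, asymmetric reward learning, higher explicit
    discounting, softmax over-exploration, random connection deletion), a battery
    of behavioral and network probes (anhedonia junction, effective-discount
    inference, hazard-approach avoidance, KL-divergence exploration comparison),
    and orchestrated experiments (variant comparison, spine restoration, decay
    sweep, simplified task) with tidy results and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
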