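Package: commonsgame
Title: Simulation and Rank-Based Norm Analysis of a Multiplayer
    Common-Pool Resource Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating a four-player common-pool resource
    dilemma with a depletable, stochastically replenished resource and
    scripted over- and under-harvesting co-players, and for analysing the
    resulting harvest adjustments.  Descriptive social norms are modelled
    as beta distributions fitted to the group's last four harvests, and a
    player's relative rank within the norm enters cubic-polynomial
    regressions of trial-to-trial harvest adjustments with
    participant-clustered bootstrap confidence intervals.  Includes a
    synthetic-participant generator with treatment-dependent policy
    parameters, endgame outcome summaries, and a 2x2 contingency
    chi-square for resource exhaustion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
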