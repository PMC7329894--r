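Package: commonpool
Title: Simulation and Analysis of a Common-Pool Resource Game with
    Collective Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A seeded simulator and analysis pipeline for a repeated
    common-pool resource game played in groups of four under three choice
    mechanisms (individual choice, median choice, and majority voting),
    with symmetric or asymmetric extraction caps. Implements the resource
    dynamics (doubling regeneration with a ceiling), the three decision
    mechanisms, a synthetic-participant generator calibrated to published
    cell means, and the downstream statistics: percentage-taken and profit
    summaries, voting-proposal analytics with an election logit, scale
    reliability (Cronbach's alpha, intraclass correlation), bootstrap
    mediation of the asymmetry effect through voting success, and
    deterministic resource-trajectory projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
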