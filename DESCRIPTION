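Package: slfspread
Title: Agent-Based Simulation of Spotted Lanternfly Spread with
    Human-Mediated Jump Dispersal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates annual spread of the spotted lanternfly (Lycorma
    delicatula) on a gridded habitat-suitability landscape with an
    agent-based model combining uniform annual adult survival, stochastic
    logistic growth, suitability-ranked Moore-neighborhood movement, and
    density-dependent human-mediated jump dispersal. Stacks replicate
    runs into per-cell occupancy probabilities, thresholds them into
    high-confidence predictions, and scores predictions against
    county-level detection records with Precision, Recall and F1.
    Includes generators for synthetic suitability surfaces, county
    tessellations and observed-spread records so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    ggplot2,
    optparse
Config/testthat/edition: 3
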