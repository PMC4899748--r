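Package: plotcarbon
Title: Fine-Scale Environment, Functional Diversity and Tree Aboveground
    Carbon in Forest Dynamics Plots
Version: 0.1.0
Authors@R:
    person("plotcarbon", "developers", email = "plotcarbon@example.org",
           role = c("aut", "cre"))
Description: Quadrat-scale analysis pipeline for large forest dynamics
    plots: terrain convexity from a corner-elevation lattice, ordinary
    kriging of soil properties with PCA reduction to a fertility axis,
    community-weighted mean traits and functional dispersion (FDis),
    moist-forest allometric aboveground biomass and carbon storage, and a
    statistical layer with Pearson correlation tables, AIC-stepwise
    regression, LMG hierarchical partitioning of R-squared and recursive
    path (structural equation) models with stepwise pruning.  Includes a
    seeded synthetic-plot generator with known ground-truth habitat
    effects so every stage is verifiable without census data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
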