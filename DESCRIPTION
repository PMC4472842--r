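Package: biofilmca
Title: Hybrid Discrete-Continuum Simulation and Quantification of
    Bacterial Biofilm Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-dimensional stochastic cellular-automaton model of
    bacterial biofilm growth coupled to a continuum equilibrium nutrient
    field and a Beer-Lambert light field. Biomass cells divide with
    Monod-kinetics probabilities and daughter cells are placed by a
    distance- and surface-energy-weighted distribution. Includes
    morphology metrics (coverage versus depth, convex-hull density,
    mean cell depth, nutrient scarcity), COMSTAT-style quantification of
    confocal image stacks with depth-adaptive thresholds, a synthetic
    confocal-stack generator, and random-forest classification and
    regression of biofilm morphologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    grDevices,
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
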