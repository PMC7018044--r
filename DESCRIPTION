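Package: flyclim
Title: Climate-Suitability Modelling for Pest Fruit Flies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A presence-background maximum-entropy species distribution
    modelling pipeline for projecting climate suitability of pest insects
    under climate-change scenarios. Implements feature construction
    (linear, quadratic, product), L1-regularized maximum-entropy fitting,
    raw/cumulative/logistic output scales, permutation importance,
    five-fold cross-validated AUC, the 10th-percentile training-presence
    threshold, multivariate environmental similarity (MESS) novelty
    detection, multi-scenario consensus mapping, multi-species hotspot
    stacking and land-area accounting. Ships a virtual-species simulator
    (spatially autocorrelated climate grids, perturbed scenario stacks
    with controllable environmental novelty, occurrence sampling from a
    known suitability truth) so the full pipeline is testable end to end
    without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
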