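Package: fsindex
Title: Forest Stability Index from Remeasured Forest Inventories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies change in relative live-tree density across remeasured
    forest-inventory plots. Fits a maximum size-density frontier (the
    self-thinning upper boundary of stems per hectare against mean tree basal
    area) as a Bayesian 99th-percentile quantile regression with forest-type
    varying intercept and slope, computes tree-level relative density and the
    forest stability index (annual change in relative density) for species and
    size-class populations, produces post-stratified annual-panel estimates of
    population change with expansion/decline/stability classification, and
    attributes change to fire, insect and disease disturbance through a
    hierarchical Bayesian severity-by-probability model. Includes a synthetic
    inventory generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
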