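Package: popdecode
Title: Inferring Coarse-Grained Decoding Weights for Correlated Neural Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring how a linear decoder weights multiple
    correlated neural populations from neuronal choice correlations and
    behavioural thresholds measured under (partial) inactivation. Implements
    two contrasting models of correlated neural variability (extensive
    information with limited-range correlations, and information-limiting
    differential correlations), their coarse-grained population-level
    descriptions, choice-probability and choice-correlation estimation from
    trial data, and a nonlinear least-squares solver that recovers per-area
    decoder scaling factors and the population-level noise covariance from
    inactivation experiments. Includes a von Mises population simulator so
    the whole pipeline can be exercised without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
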