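Package: harmonium
Title: Deep Belief Network Simulation of Meaning-Space Dimensionality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework linking the internal computational
    dynamics of a deep belief network to its classification performance.
    Generates entropy-controlled letter stimuli from a procedural glyph
    registry, trains stacked restricted Boltzmann machines by one-step
    contrastive divergence with a delta-rule read-out, records the second
    hidden layer's activation trajectory across learning cycles, condenses
    it into windowed standard-deviation micro-stages, and measures the
    dimensionality of those dynamics with correlation-scale principal
    component analysis (weight of the primary and secondary dimensions).
    Includes the standardized multiple regressions and Welch/paired t-test
    checks relating dimensionality indicators to per-letter accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), png, yaml, optparse, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
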