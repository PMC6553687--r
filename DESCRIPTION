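Package: phyllofield
Title: Inhibitory-Field Models of Phyllotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of phyllotactic patterning with
    inhibitory-field models of the shoot apical meristem. Implements the two
    classical Douady-Couder formulations (a discrete one-per-plastochron model
    on a planar apex and a continuous-time threshold model on a conical apex)
    together with their expansions in which the inhibitory power of a
    primordium changes sigmoidally with its age. Provides divergence-angle and
    plastochron extraction, classification of emergent patterns (distichous,
    spiral, decussate, tricussate, orixate and x-cycle types) with a
    colour-legend encoding, parameter-space sweeps, and numerical stability
    analyses of the normal orixate arrangement, including condition-curve
    solving for the expanded discrete model and an impossibility scan for the
    plain one.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
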