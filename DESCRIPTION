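Package: gridtether
Title: Boundary-Tethered Grid Cell Network Model and Deformation Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spiking network model coupling border cells, velocity-driven
    continuous-attractor grid modules and place cells through competitive
    Hebbian learning, together with the spatial-map analysis toolbox needed
    to study how environmental deformations distort grid and place codes:
    occupancy-normalised rate maps, masked auto/cross-correlograms, grid
    scale and gridness scores, boundary-conditioned rate maps with
    occupancy-matched subsampling, grid-shift and rescaling statistics,
    boundary-tethered rate-map prediction and population-vector correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
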