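Package: vesselquant
Title: Quantitative Image Analysis for Microvessel-on-Chip Extravasation Assays
Version: 0.1.0
Authors@R:
    person("Vesselquant", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable, tested pipeline for quantifying microfluidic
    endothelial-vessel assays from fluorescence microscopy: diffusive
    vascular permeability from dextran time-lapse stacks via a mass-balance
    estimator, interstitial flow velocity from photobleached-spot (FRAP)
    tracking with conversion to Darcy hydraulic permeability, a Fourier
    alignment index for actin and junction textures, endothelial-monolayer
    continuity and vessel diameter measurement, and adhered/extravasated
    monocyte scoring in 3D nuclear stacks. Includes a synthetic-phantom
    generator with known ground truth so every stage is verifiable by
    parameter recovery, plus condition-level statistical reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
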