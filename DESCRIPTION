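Package: trochwarp
Title: Slice-Based Morphometry and Tension-Band Force Modelling of the
    Greater-Trochanter Growth Plate
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the ventro-dorsal warp of the apophyseal
    growth plate of the greater trochanter. Generates synthetic proximal-femur
    phantoms with a planted per-layer plate inclination profile, emulates
    frontal and axial MRI slice stacks with calibration-slice indexing,
    measures the layer-stratified AY angle (plate inclination to the body
    horizontal), computes straight-line muscle trajectories in the frontal and
    transverse planes, and evaluates a PCSA-weighted tension-band force model
    (internal, external and posterior systems with a periosteal counterforce)
    that predicts the regional plate orientation from the perpendicularity
    principle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
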