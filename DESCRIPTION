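Package: cellmech
Title: Micropillar Traction Force, Laurdan GP Membrane Fluidity and Cell
    Motility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible analysis chain for biophysical single-cell
    measurements: per-pixel laurdan generalized polarization (GP) maps of
    membrane fluidity with Gaussian-fitted frequency distributions and
    condition-difference curves; micropillar traction force microscopy
    (subpixel pillar localization, lattice reconstruction, time-lapse
    tracking, reference-pillar drift correction and Euler-Bernoulli
    beam-theory forces); equivalent-ellipse cell morphometry and
    single-cell migration track metrics; and fold-change filters for
    gene-expression and metabolite tables. A synthetic-data module
    generates pillar-array movies, two-channel laurdan scenes, cell
    tracks and omics tables with known ground truth so that every
    analysis stage can be validated against planted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
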