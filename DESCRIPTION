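Package: riboscreen
Title: Colony-Array Riboswitch Biosensor Screens and Reporter Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of genome-scale riboswitch-biosensor fluorescence
    screens on high-density pinned colony arrays and of plate-reader
    reporter kinetics. Quantifies paired white-light/fluorescence plate
    images into per-colony integrated intensities, computes spatially
    corrected fluorescence/biomass ratios, combines replicates, normalizes
    a wild-type reporter screen by a ligand-blind binding-mutant control
    screen into a per-strain expression index centered at 1, and calls
    hits beyond 1 +/- k standard deviations. A companion kinetics module
    derives fluorescence/OD expression values at the exponential midpoint
    and in stationary phase, fold regulation against a no-ligand
    reference, and dose-response summaries. A synthetic-data module
    generates colony-array images and growth curves with planted ground
    truth so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    png,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
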