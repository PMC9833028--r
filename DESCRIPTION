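Package: mdmsim
Title: Digital Twin for a Magnetic Digital Microfluidic Immunoassay Chip
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models a magnetic digital microfluidic (MDM) immunodiagnostic
    chip and its magnet-driven droplet manipulations. Provides a chip-layout
    data model with a built-in four-unit bead-based ELISA chip, a grammar and
    validator for magnet motion protocols over a layer-by-keypoint grid, a
    discrete-event simulator of droplet movement, merging, mixing and
    magnetic microbead extraction with stochastic retention losses, mixing
    index and homogeneity kinetics calibrated to active and passive mixing
    anchors, a synthetic sandwich-ELISA signal model and chip-image renderer,
    and an image-based quantification pipeline (inverse-blue intensity,
    per-unit calibration curves, QC filtering, linear standard curves and
    limit-of-detection estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
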