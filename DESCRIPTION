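Package: svopsim
Title: Simulation of Threshold Saccadic Vector Optokinetic Perimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fully simulatable model of threshold saccadic vector
    optokinetic perimetry (SVOP), an eye-tracking alternative to standard
    automated perimetry (SAP) in which stimulus perception is inferred from
    the direction and amplitude of the saccadic gaze response instead of a
    button press. Provides the 24-2 test-pattern geometry and the perimetric
    decibel/luminance scale, gaze-contingent stimulus projection with
    head-position compensation, saccadic response classification, a 4-2
    bracketing threshold engine with quadrant seed points and
    neighbour-propagated starting levels, a synthetic patient and eye-tracker
    model (hill-of-vision and glaucomatous sensitivity fields,
    frequency-of-seeing responses, oculomotor and tracking noise), and the
    agreement and test-retest repeatability analyses used to validate such
    instruments against standard automated perimetry.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
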