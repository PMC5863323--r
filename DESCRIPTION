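Package: magecalc
Title: Automated Mean Amplitude of Glycemic Excursions (MAGE) from
    Continuous Glucose Monitoring Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes the mean amplitude of glycemic excursions (MAGE) and
    related glycemic-variability statistics (SDBG, MAGE+, MAGE-, MAGEa) from
    continuous glucose monitoring (CGM) traces. Excursion counting is posed
    as an integer nonlinear program: select an alternating subsequence of
    local extreme points whose adjacent amplitudes all exceed the standard
    deviation of blood glucose, maximizing first the number of selected
    points and then the total amplitude. Exact solvers (exhaustive
    enumeration and dynamic programming) are provided as oracles alongside
    an integer differential-evolution solver with penalty-function
    constraint handling. Includes CSV import with unit conversion and 24-hour
    segmentation, plateau-merging extreme-point detection, synthetic trace
    generators with known ground truth, plotting, and a command-line script.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
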