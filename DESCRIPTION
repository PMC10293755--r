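Package: thermospread
Title: Lateral Thermal Spread Measurement from Radiometric Thermogram Sequences
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies lateral thermal spread of bipolar electrosurgery from
    temperature-calibrated infrared image sequences. Segments pixels exceeding
    a tissue-damage temperature threshold (default 60 degrees Celsius) over a
    whole recording, converts pixel counts to square millimetres using an
    in-scene fiducial of known length, and summarises cohorts with
    nonparametric statistics (median/IQR, exact Wilcoxon rank-sum, Spearman
    correlation, least-squares fits). Includes a finite-difference bioheat
    simulator and a microbolometer camera model that generate fully synthetic
    cohorts with known ground truth, so the complete analysis pipeline is
    testable without physical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
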