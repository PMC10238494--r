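Package: mrmpanel
Title: Surrogate-Peptide Library Construction and MRM Biomarker Panel
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for building targeted-proteomics (MRM)
    surrogate-peptide libraries and carrying biomarker candidates through a
    two-stage discovery/validation cascade, analytical performance
    evaluation, and hold-out classifier assessment. Includes rule-based
    in-silico tryptic digestion with proteotypic candidate scoring,
    chromatogram peak detection with signal-to-noise screening,
    stable-isotope internal-standard quantification, calibration-curve and
    precision acceptance checks, and a simulation suite that generates
    blood-proteome-like inputs with known ground truth so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
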