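Package: sbrtTCP
Title: Dose-Algorithm Sensitivity of Tumour Control Probability for SBRT
    Targets at Tissue Interfaces
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify how differences between photon dose-calculation
    algorithms at low-density tissue interfaces (such as the lung-liver
    boundary) propagate into planning-target-volume dose metrics and
    2-year tumour control probability (TCP) for stereotactic body radiation
    therapy (SBRT). Provides cumulative dose-volume histogram (DVH)
    computation from 3-D dose grids and structure masks, target splitting by
    tissue, Dx% metric extraction, linear-quadratic biologically effective
    dose (BED) conversion, a logistic TCP model, exact and approximate paired
    Wilcoxon signed-rank tests, and a seeded synthetic phantom-cohort
    generator that emulates paired dose grids whose discrepancy is
    concentrated in the low-density portion of the target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
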