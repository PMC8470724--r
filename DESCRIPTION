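Package: ngmscreen
Title: Untargeted Metabolomics Screening Pipeline for Inborn Errors of
    Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the computational stages of a next-generation
    metabolic screening (NGMS) workflow for diagnosing inborn errors of
    metabolism from untargeted LC-QTOF-MS plasma profiles: elemental
    formula, adduct and 13C-isotopologue m/z arithmetic with ppm matching;
    cross-injection mass-feature alignment; two-tier metabolite annotation
    against a diagnostic panel (m/z and retention time) and a compound
    library (m/z only); single-patient outlier statistics (duplicate
    averaging, fold change versus the batch median, robust z-scores);
    analytical quality control, validation-plasma gating and release
    regression comparison; and an interpretation engine with filter
    presets, bar-plot data, review states and an append-only audit trail.
    A deterministic batch simulator stands in for the mass spectrometer so
    that every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    mzR,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
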