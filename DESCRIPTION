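Package: scaspd
Title: Scoring and Psychometric Validation of the SCAS-PD Swallowing Assessment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Swallowing Clinical Assessment Score in
    Parkinson's Disease (SCAS-PD), a 12-item weighted bedside instrument for
    dysphagia administered over three food offerings (liquid, paste, solid),
    together with the statistical battery used to validate such instruments
    against videofluoroscopy (VFSS): Cronbach's alpha internal consistency,
    intraclass correlation, linear and quadratic weighted kappa, per-level
    Cohen's kappa, empirical ROC curves with DeLong or bootstrap confidence
    intervals, and Youden-index cutoff selection. A seeded synthetic cohort
    generator produces paired (assessment, VFSS label) data with a
    configurable severity distribution and index-test/gold-standard
    concordance so the full validation pipeline can be exercised and tested
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
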