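Package: vitalsynth
Title: Vital-Rate Evidence Synthesis and Matrix Population Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesises published vital-rate estimates for stage-structured
    demographic models, with an application to the common eider (Somateria
    mollissima). Provides a screened evidence-database format, simple-mean and
    mean-adjusted precision-weighted random-effects meta-analysis (including
    sub-meta-analysis of spatiotemporal replicates within studies), assembly of
    a six-stage prebreeding female projection matrix with a discrete reversible
    nonbreeder stage, asymptotic perturbation analysis (growth rate, stable
    structure, reproductive values, sensitivities and elasticities), and a
    quantitative comparison of per-transition study effort against
    per-transition demographic importance, including the closed-form null for
    chance over- and under-representation and a simplex null simulation.
    Includes a synthetic-database generator with known ground truth for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
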