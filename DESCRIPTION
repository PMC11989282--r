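Package: msiclone
Title: Microsatellite Instability Scoring, Clonality Estimation and
    Outcome Modelling from STR Length Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calls microsatellite instability (MSI) from amplicon NGS
    read-length histograms over a panel of short tandem repeats (STRs),
    quantifies MSI clonality as a linear transform of the mean area by
    which a sample's STR length distributions exceed a stable-reference
    envelope, and analyses diagnostic concordance (Cohen and Fleiss
    kappa), exact response statistics (Clopper-Pearson intervals,
    Barnard and Fisher exact tests), a composite non-responder score,
    and progression-free survival via penalized Weibull accelerated
    failure time regression with AIC-based penalizer selection. A
    synthetic-data module generates reference profiles, tumor and
    plasma mixtures with PCR stutter, and full patient cohorts so the
    whole pipeline can be exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
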