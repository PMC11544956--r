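Package: bePLSDA
Title: Paired-Design PLS-DA with VIP Backward Elimination for NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric workflow for detecting illicit preservative
    treatment of fish from handheld near-infrared (NIR) spectra. Implements
    spectral pretreatments (standard normal variate, Savitzky-Golay
    derivatives, paired-day centering, autoscaling), a from-scratch
    two-class PLS-DA (NIPALS) with variable importance in projection (VIP)
    scores, VIP-driven backward elimination wrapped around grouped
    leave-more-out cross-validation respecting the paired-day study design,
    and a synthetic paired-design spectra generator with known ground truth
    so every stage of the pipeline is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    signal,
    mixOmics,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
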