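Package: pairsig
Title: Rank-Based Gene-Pair Prognostic Signatures for Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and validation of prognostic signatures built from
    binary within-sample gene-pair indicators (I(expr[A] > expr[B])) in bulk
    tumor transcriptomes. Provides differential-expression screening across
    tumor/normal, metastatic/non-metastatic and immune-infiltration contrasts,
    single-sample gene-set enrichment (ssGSEA) immune scoring with
    hierarchical immune-group clustering, pair-indicator construction with a
    prevalence validity filter, univariate and LASSO-penalized Cox selection
    with an unpenalized refit, time-dependent ROC cut-off selection,
    Kaplan-Meier risk-group evaluation, and a synthetic-cohort generator with
    full ground truth so every stage is testable without external data.
    Ships a published three-pair colorectal-cancer signature
    (C6orf15|PCSK1, CTSW|FABP4, SPRR1B|PCSK1) as a fixed scorer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
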