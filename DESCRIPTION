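Package: ovorisk
Title: Elemental Profiling, Dietary Risk Scoring and Chemometric
    Classification of Egg Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for multi-element (ICP-MS style) concentration data from
    chicken egg components (egg white, yolk, eggshell). Converts acid-digest
    solution measurements to dry-weight tissue concentrations, computes
    per-metal Target Hazard Quotients (THQ) and their sum (TTHQ) for
    non-carcinogenic dietary risk assessment, performs principal component
    exploration with Mahalanobis score-distance outlier trimming, and fits
    sparse partial least squares discriminant analysis (sPLS-DA) models with
    keepX variable selection, repeated stratified cross-validation on overall
    and balanced error rates, and held-out evaluation, to discriminate egg
    components and hen rearing systems. A calibrated lognormal/Gaussian-copula
    generator produces synthetic egg-composition datasets with non-detects and
    injected outliers so the whole pipeline is testable without measured data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.3.0),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
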