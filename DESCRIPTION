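Package: coixcal
Title: GC-IMS-Guided Near-Infrared Calibration of Storage Deterioration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric workflow for monitoring storage deterioration of
    processed coix seeds by near-infrared spectroscopy (NIRS) guided by gas
    chromatography-ion mobility spectrometry (GC-IMS). Provides internal-
    standard normalization and monomer/dimer deduplication of GC-IMS peak
    tables, OPLS-DA marker screening with VIP scores, construction of
    composite flavor and deterioration indices from PLSR latent scores,
    NIRS preprocessing (SNV, MSC, Savitzky-Golay derivatives, Min-Max),
    NIPALS PLS1 calibration with cross-validated latent-variable selection,
    and permutation-test validation via the Q2 intercept. Includes a
    synthetic-data generator emulating the spectral and volatile-compound
    structure of a storage study so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    e1071,
    randomForest,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
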