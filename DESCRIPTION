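Package: sporoquant
Title: Quantification Pipelines for Intercellular Metabolite Exchange in
    Sporulating Bacillus subtilis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify metabolic differentiation and mother-cell to
    forespore metabolite trafficking during Bacillus subtilis sporulation.
    Provides membrane-channel segmentation of sporangia with
    forespore/mother-cell pairing, per-cell fluorescence ratiometry and
    volume normalization, reporter depletion time courses, BONCAT
    protein-synthesis quantification, engulfment and phase-bright spore
    scoring, FRAP/FLIP photobleaching analysis with corrected fluorescence
    recovery (cFR) and acquisition-bleaching standard curves, a
    two-compartment intercellular exchange model with exchange-rate
    estimation, and cell-specific SILAC heavy-arginine peptide
    classification with regulon-based compartment assignment. Seeded
    synthetic-data generators emit ground-truthed microscopy images,
    photobleaching traces and peptide tables against which every estimator
    is validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
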