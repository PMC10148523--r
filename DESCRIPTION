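Package: acceptindex
Title: Construction and Validation of Maternal Healthcare Acceptability Indices
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds composite acceptability-of-care indices from ordinal
    questionnaire data scored on a three-point scale. Implements the full
    measurement pipeline for three-construct (provider, healthcare system,
    community) instruments: codebook-driven rescaling with neutral imputation,
    suitability diagnostics (Bartlett sphericity, Kaiser-Meyer-Olkin),
    principal-factor exploratory analysis with eigenvalue retention,
    cross-loading pruning and factor naming, maximum-likelihood confirmatory
    factor analysis with a standard fit-index panel (RMSEA, CFI, TLI, SRMR, CD),
    a reliability and validity battery (Cronbach's alpha, composite
    reliability, average variance extracted, maximum shared variance),
    simple-arithmetic acceptability indices on a 0-100 scale, a seeded
    synthetic-data generator for ordinal items with latent factor structure,
    and a standardized measurement-tool report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
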