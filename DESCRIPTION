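Package: metalrisk
Title: Heavy-Metal Pollution Indices and Ecological Risk for Farmland Soil Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assessment of heavy-metal contamination in layered farmland soil.
    Computes the classical pollution and ecological-risk index systems for the
    seven regulated metals (Cr, Ni, Cu, Zn, As, Cd, Pb): single-factor
    pollution indices, the Nemero comprehensive index, the geometric-mean
    pollution load index, the geoaccumulation index, and Hakanson single and
    total potential ecological risk indices, each with its grading scheme.
    Provides per-layer descriptive statistics with exact rank and Welch
    two-group tests, Pearson correlation with significance stars, PCA with
    per-axis contribution ranking, supervised UMAP embedding with group
    confidence ellipses, a stepwise linear model suite quantifying variable
    contributions to total ecological risk with LMG importance decomposition,
    and a moment-matched synthetic generator for two-layer multi-site soil
    chemistry tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml,
    jsonlite,
    uwot
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
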