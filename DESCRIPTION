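Package: phenoscreen
Title: Multi-Parametric Phenotypic Scoring of Drug Effects in High-Content Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing drug effects on cultured cells from
    multi-channel fluorescence screens. Segments nuclei and whole cells from
    three-channel fields (nucleus, actin, tubulin), quantifies per-cell
    morphological and intensity attributes, scores treated cells against a
    robust-PCA control hyper-ellipsoid by Mahalanobis distance with outlier
    rejection and per-attribute contribution ranking, fits median-effect
    (Chou) dose-response curves, and analyses binary drug combinations under
    Loewe additivity and Bliss independence. Includes a synthetic-data
    generator producing ground-truthed image fields and correlated per-cell
    feature populations, plate-layout modelling for 384-well screens, and a
    command-line workbench for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    minpack.lm,
    EBImage,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
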