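Package: tibmorph
Title: Automated Micro-CT Morphometry of Murine Tibial Epiphyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated analysis of micro-computed-tomography scans of the
    proximal tibial epiphysis in mouse models of osteoarthritis. Provides
    rigid surface (iterative-closest-point) registration of paired bones,
    macro-porosity-based partition of subchondral bone into plate and
    trabecular compartments with volumetric and densitometric quantification,
    model-independent local-thickness heat maps and medial-lateral profiles,
    osteophyte volumetry by registered shape subtraction and by whole
    epiphyseal volume, the agreement and precision statistics used to
    validate such methods (Pearson/Spearman correlation, RMS error from
    regression residuals, coefficient of variation, Bland-Altman limits of
    agreement), and a synthetic epiphysis phantom generator with exact
    ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    jsonlite
Config/testthat/edition: 3
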