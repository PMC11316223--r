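Package: fibromorph
Title: Automated Morphotyping of Fibroblasts on Protein Micropatterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An automated image-analysis pipeline for quantifying fibroblast
    morphological state ("morphotype") from multi-channel fluorescence
    microscopy of cells on micropatterned substrates. Provides image
    preprocessing (maximum projection, percentile autocontrast, white top-hat
    filtering), three-level segmentation (nuclei as primary objects, cells as
    seeded secondary objects, focal adhesions as masked tertiary objects),
    a 40-parameter morphometric feature catalog with two-point phenotype-axis
    normalization, Shapley-value feature-importance ranking with an exact
    enumeration oracle, focal-adhesion-to-nucleus spatial statistics, cell and
    actin-fiber orientation analysis, Hertz-model fitting of atomic force
    microscopy indentation curves, and delta-delta-Ct relative quantification
    for qPCR. A synthetic-scene generator with full ground truth supports
    validation without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    tools,
    pracma,
    xgboost,
    ggplot2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
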