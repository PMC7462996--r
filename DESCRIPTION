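Package: rpeqc
Title: Image-Based Quality Evaluation of iPSC-Derived Retinal Pigment
    Epithelium Sheets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric quality evaluation of retinal pigment epithelium
    (RPE) monolayers from cell-label images. Extracts eight per-cell shape
    descriptors (area, perimeter, compactness, inscribed and enclosing
    radius, length, width, length-width ratio) from integer label images,
    aggregates them into bootstrap sample profiles (mean and standard
    deviation of each feature), removes discordant samples by hierarchical
    clustering against transepithelial electrical resistance (TER) groups,
    and fits L1-penalised (LASSO) models that predict TER in Ohm.cm2 and
    discriminate high- from low-TER sheets, with leave-one-out
    cross-validation. A seeded synthetic epithelium generator (Voronoi
    tessellation with Lloyd relaxation) couples sheet morphology to a
    ground-truth TER so the whole pipeline is testable without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
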