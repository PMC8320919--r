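Package: her2feat
Title: Biomarker-Specific Image Features for HER2 Scoring of IHC Histology Tiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification for automated HER2 scoring of
    immunohistochemistry (IHC) stained histology image tiles. Computes
    characteristic curves (percentage of DAB-stained pixels as a function of a
    saturation threshold), rotation-invariant uniform local binary pattern
    (ULBP) feature curves, a region-connectedness measure based on the largest
    stained connected component, and entropy/energy statistics of the CIE-Lab
    b* channel histogram. Features are reduced to a 38-dimensional descriptor
    and classified with one-vs-all logistic regression or support vector
    machines. Includes a synthetic tile generator emulating class-dependent
    membrane-like staining for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    igraph,
    glmnet,
    e1071,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    withr
Config/testthat/edition: 3
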