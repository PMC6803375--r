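Package: fabquant
Title: Quantification of Histone-Modification Live Imaging in Early Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying Fab-based live endogenous modification
    labeling (FabLEM) movies of early embryos: single-nucleus segmentation
    and tracking from a nuclear-marker channel, nucleus-to-cytoplasm (N/C)
    intensity ratios measured with physical-distance cytoplasmic ring masks,
    detection and quantification of intranuclear foci (foci/nucleus ratios
    and peak-time ordering), and double-exponential fitting of fluorescence
    recovery after photobleaching (FRAP) curves. Includes a ground-truthed
    synthetic embryo-movie generator so that every stage of the pipeline can
    be exercised and validated without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    xml2,
    minpack.lm,
    readr,
    jsonlite,
    yaml,
    igraph,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
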