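Package: zymopore
Title: Linking Soil Pore Architecture to Enzyme Activity Maps from
    X-ray Micro-CT and Zymography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the micro-scale image-analysis chain that connects
    soil pore architecture, imaged by 3D X-ray computed micro-tomography,
    to the spatial distribution of extracellular enzyme activity, imaged
    by 2D soil zymography.  Includes grayscale preprocessing and
    two-Gaussian minimum-error histogram segmentation of CT volumes,
    continuous pore-size distributions by maximal inscribed spheres
    (local thickness), the microbial spatial footprint (soil matrix
    within a set distance of sizeable pores) via exact Euclidean
    distance transforms, zymogram masking and standardization, and
    co-registration of 2D enzyme maps with 3D pore data on a 1-mm grid
    with percentile-based micro-site selection.  A synthetic-core
    generator produces CT phantoms and paired zymograms with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    png,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
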