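Package: rastermapr
Title: One-Dimensional Sorting of Neural Population Activity for Raster Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sorts large neural population recordings (neurons by timepoints,
    or trials by features) along one dimension so that nearby rows have
    similar activity, producing interpretable raster plots. The sorting uses
    scaled k-means clustering in a reduced singular-vector space, an
    asymmetric peak-lag cross-correlation similarity between cluster traces,
    and a travelling-salesman-style segment-move optimization of the
    similarity matrix against a heavy-tailed matching matrix, followed by
    upsampling of cluster centers to assign each neuron a continuous
    embedding position. Also included are synthetic benchmark generators
    with known ground truth (sequence, tuning, sustained and power-law
    eigenspectrum modules; a purely power-law population; a two-dimensional
    place-field population) and embedding-quality metrics (triplet score,
    module contamination, k-nearest-neighbor preservation, local/global
    similarity-matrix scores).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
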