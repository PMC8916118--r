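Package: tomomorph
Title: Morphometry and Spatial Statistics for Cryo-Electron Tomography
    Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of annotations derived from cryo-electron
    tomograms of neuronal processes: filament morphometry (fixed-spacing
    resampling, arc length, orientation against a reference axis),
    three-dimensional nearest-neighbour analysis of ribosome picks with
    Gaussian histogram fitting and polysome/monosome classification,
    organelle measurement summaries with exact Mann-Whitney rank-sum
    testing and region enrichment, and a minimal subtomogram-averaging
    engine with missing-wedge compensation, half-set averaging and Fourier
    shell correlation resolution estimation. A synthetic-data generator
    reproduces the statistical structure of such annotation sets so every
    stage of the pipeline can be exercised and validated without
    tomographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
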