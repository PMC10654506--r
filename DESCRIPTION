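Package: retinotile
Title: Single-Cell Retinotopy Analysis of the Retinocollicular Projection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the precision of retinotopic maps at
    single-cell resolution, built around the mouse retinocollicular
    projection. Implements receptive-field estimation by reverse
    correlation with 2D Gaussian fitting, the Delaunay tiling-pattern
    match statistic with a permutation (bootstrap) chance level, the
    affine-optimal retinotopy deviation, and a generative jittered-lattice
    model of the retinal ganglion cell to superior colliculus projection
    whose inversion yields the axonal projection jitter (sigma) and the
    mean input convergence (lambda) with 95% confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
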