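Package: symfruit
Title: Symmetry-Based Completion of Occluded Fruit Point Clouds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for restoring the full three-dimensional shape of
    partially occluded fruit point clouds, as encountered in canopy-level
    laser scans of greenhouse crops. The package detects a fruit's symmetry
    plane from partial data by combining RANSAC ellipsoid fitting, principal
    component analysis and an adaptive mirror-matching refinement loop built
    on iterative closest point alignment, then constructs a triple-orthogonal
    symmetry system and fills missing regions by constrained mirroring with
    voxel fusion. Includes preprocessing filters, fruit segmentation by
    region growing, occlusion-rate estimation from reconstructed surface
    area, a synthetic fruit generator with programmable occlusion patterns
    for validation, and evaluation utilities (R squared, RMSE, relative
    RMSE, paired signed-rank tests) for benchmarking completion accuracy
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    interp,
    jsonlite,
    purrr,
    RANN,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
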