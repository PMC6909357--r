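Package: celltrax
Title: Automated Cell Tracking and Motility Analysis for 3D Chemotaxis
    Time-Lapse Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis workflow for phase-contrast time-lapse videos of cells
    migrating in 3D collagen gels. Implements background subtraction by
    average-intensity projection with saturation-bounded contrast
    normalization, Laplacian-of-Gaussian cell detection with sub-pixel
    localization, two-pass linear-assignment tracking with gap closing, and
    trajectory motility statistics (cell speed, directionality ratio,
    time-averaged mean squared displacement) with origin-aligned trajectory
    plots and Mann-Whitney condition comparisons. Includes a synthetic
    migrating-cell video generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
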