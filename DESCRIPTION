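Package: numerispec
Title: Aggregate Fourier Power and Numerosity Response Models for Dot Displays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how the number of items in a visual display is
    reflected in low-level image statistics and in fMRI responses. Renders
    parametric numerosity displays (constant-area, constant-size,
    constant-perimeter and high-density configurations, polygons, stars and
    connected dot pairs), computes the radial Fourier power spectral density of
    a display with automatic detection of the first-harmonic limit, and
    summarises each display by its normalized aggregate Fourier power together
    with a battery of candidate non-numerical features (areas, perimeters,
    convex-hull statistics, contrast energies and Laplacian-of-Gaussian filter
    responses). Builds stimulus sequences for a block fMRI design, fits
    monotonic (general linear model) and tuned (logarithmic Gaussian) response
    models to voxel time series with split-half cross-validation, simulates
    synthetic voxel cohorts with known ground truth, and provides
    eccentricity-profile fitting with bootstrap confidence intervals and
    model-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
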