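Package: cochleogram
Title: Longitudinal Transduction-Rate Profiles for Whole-Mount Cochleas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns point annotations of transduced cells in whole-mount
    cochlea images into longitudinal transduction-rate profiles
    ("cochleograms"). Fits an arc-length-parameterized spline to an
    operator-delineated cochlear axis, projects annotated cells onto it,
    smooths the resulting longitudinal coordinates with a boundary-corrected
    Gaussian kernel density, and converts densities to per-cell-type
    transduction fractions using reference longitudinal cell densities.
    Includes fragment merging for cut cochleas, Kolmogorov-Smirnov and
    Welch comparisons of profiles, and a synthetic-cochlea generator with
    known ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
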