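Package: mrordenoise
Title: Impulse-Noise Detection and Non-Local Means Restoration for
    Mammogram Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage removal of impulse noise from 8-bit grayscale
    mammograms and similar images. Pixels are graded by a windowed robust
    outlyingness statistic (the modified robust outlyingness ratio, the
    studentized deviation of a pixel from the median of its 5x5
    neighbourhood, scaled by a normalized median absolute deviation) and
    partitioned into four noise-likelihood clusters with per-cluster
    decision thresholds. Detection runs as an iterative coarse-then-fine
    cascade in which an adaptive fuzzy median filter restores flagged
    pixels between iterations. Restoration of the detected pixels uses a
    mask-aware non-local means filter driven by the cascade's restored
    image as reference, so never-flagged pixels pass through untouched.
    Includes an impulse-noise simulator (salt-and-pepper and
    random-valued), a seeded mammogram-like phantom generator, standard
    and adaptive median baselines, and a PSNR/MSE benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    png,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
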