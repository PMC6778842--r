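Package: stainkit
Title: Fast and Robust Stain Normalization for H&E Histopathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Optimized Macenko stain normalization for hematoxylin-and-eosin
    (H&E) histology images. Estimates per-image stain vectors and robust
    maximum stain concentrations in optical-density space, with an automatic
    Otsu background threshold computed at low resolution, look-up-table
    RGB-to-OD conversion, single-pass covariance from component sums,
    selection-based (partial-sort) percentiles, and Monte Carlo pixel
    sampling. A dataset-level quality-control mode cross-checks the eight
    estimated parameters across a slide set, flags poor-quality images whose
    parameters fall outside acceptable ranges, and replaces their parameters
    with a representative set averaged over the good-quality images before
    projecting every image onto a common reference template. Includes a
    synthetic H&E image generator (Beer-Lambert linear mixing of two known
    stain vectors with background and artifact blobs) so the whole pipeline
    is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
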