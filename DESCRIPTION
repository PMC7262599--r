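Package: centrotrack
Title: Centrosome Dynamics Quantification in Time-Lapse Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies centrosome separation, congression and nuclear
    positioning from multi-channel time-lapse fluorescence movies.
    Provides difference-of-Gaussians spot detection with circularity
    filtering, watershed nuclear segmentation and Gabor-texture cell
    segmentation, particle linking with nearest-neighbour, drift and
    Kalman motion models, and the derived statistics used in centrosome
    biology: distance and speed series, mean-squared displacement with
    high/low displacement grouping, centroid angles, congression
    percentages, nuclear-envelope contact phases and line-profile
    quantification of perinuclear signal. A synthetic movie generator
    with ground-truth tables makes every stage testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
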