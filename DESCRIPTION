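Package: braggnet
Title: Simulated Diffraction Images and Single-Image Quality Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of macromolecular X-ray diffraction images under
    the kinematic approximation, with controllable Debye-Waller B factor,
    background, detector noise, masks and one to three overlapping crystal
    lattices; exact block-maximum/square-root image conditioning into
    beam-anchored 512x512 quadrants; residual-network-style regression and
    classification models with a geometry-aware inverse-resolution output stage,
    including a desk-scale trainable variant; and per-image inference with
    quadrant aggregation, overlap-probability thresholding and data-set
    summaries for diffraction monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
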