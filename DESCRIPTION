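Package: bollcount
Title: Plot-Level Cotton Boll Counting from Aerial RGB Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates plot-level cotton yield from aerial RGB imagery of
    defoliated breeding trials. Provides color-index background removal
    (a modified excess-green-minus-excess-red vegetation index and a
    CIELAB-based soil index), support-vector-machine pixel classification
    of cotton bolls over RGB/HSV/CIELAB features with recursive feature
    elimination, morphological post-processing with 8-connected component
    counting, regression-based evaluation of predicted versus ground-truth
    boll counts, and genotype comparison via one-way ANOVA with Fisher's
    LSD letter groups. Includes a synthetic plot-scene generator with
    known per-pixel class truth so the whole pipeline can be exercised
    and validated without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    mgcv,
    png,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
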