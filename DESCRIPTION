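Package: fundtess
Title: Fundus Tessellated Density from Color Fundus Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies fundus tessellated density (FTD), the fraction of the
    imaged fundus occupied by exposed choroid, from 45-degree color fundus
    photographs. Provides the full measurement pipeline (region-of-interest
    extraction, frequency-domain denoising, LAB lightness normalization,
    contrast-limited adaptive histogram equalization, channel-subtraction
    auto-labeling, and a trainable convolutional segmentation model), exact
    density and confusion-matrix metrics, a seeded synthetic fundus-image
    generator with ground-truth masks, and a calibrated synthetic cohort
    generator together with the univariate screen, VIF-pruned stepwise
    multivariate regression and stratified summaries used to study the
    epidemiology of FTD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    jpeg,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
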