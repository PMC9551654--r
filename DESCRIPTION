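Package: lodgepoint
Title: Crop Lodging Assessment from UAV Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for assessing crop lodging from UAV-derived field point
    clouds. Separates ground from vegetation with the Excess Green index,
    normalizes heights against an interpolated digital elevation model,
    aligns plots to their principal axes (Hotelling transform), rasterizes
    canopy height with inverse-distance-weighted interpolation into 2D
    images, scores plots with a lodging index and a double-threshold
    four-class scheme, and trains convolutional neural network classifiers
    (AlexNet, VGG16, MobileNetV2) of lodging degree. Includes a synthetic
    wheat-field generator with known ground truth so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
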