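Package: fluoarea
Title: Contamination Area Quantification from Orthogonal Photographs
Version: 0.1.0
Authors@R: person("fluoarea", "maintainers", email = "maintainers@fluoarea.dev",
    role = c("aut", "cre"))
Description: Quantifies the physical area (mm^2) of fluorescent-dye
    contamination on a flat surface from a smartphone photograph taken at a
    known distance along the surface normal. Converts the photograph to
    grayscale, binarizes it with Otsu's maximum-interclass-variance
    threshold, and maps the white-pixel fraction to a physical area either
    through a single-reference lambda calibration or through
    distance-indexed least-squares calibration curves with linear
    interpolation between calibrated distances. Includes a pinhole-model
    synthetic scene generator with exact ground-truth masks, a distance
    sensitivity sweep, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    jpeg,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
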