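Package: thermaltrack
Title: Detection, Recognition and Tracking of Wildlife in Aerial Thermal Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for automated detection and recognition of warm-bodied
    animals in top-view thermal image sequences, as recorded from a lift or
    unmanned aerial vehicle over agricultural fields. Hot objects are
    segmented with a per-frame dynamic threshold (median temperature plus a
    fixed offset), each detection is described by a thermal signature
    obtained by iterative morphological contour peeling, the signature is
    parameterized by truncated discrete cosine transform coefficients, and a
    k-nearest-neighbour classifier separates animals from hot distractors
    such as halogen lamps and molehills. A lightweight multi-frame tracker
    links detections through guess regions and accumulates a per-track
    animal belief by recursive Bayesian updating of the clamped kNN
    likelihood ratio. Includes a ground-truthed synthetic thermal-scene
    generator (animals, lamps, molehills, altitude sweeps with inverse-square
    pixel footprints), evaluation metrics (balanced accuracy, detection
    performance, altitude-range reports) and raster input/output with
    bit-exact temperature reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    class,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
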