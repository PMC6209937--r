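Package: needleloc
Title: Needle Localization in Paired Power Doppler and B-Mode Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automatic localization of a straight biopsy needle in a
    co-registered pair of 2D ultrasound images: a power Doppler image of the
    buzzer-excited needle and a conventional B-mode image. The power Doppler
    image is thresholded (iterative intermeans), clustered (DBSCAN) and scanned
    with a discrete Radon transform to obtain an initial needle axis and
    elliptical candidate regions; the B-mode image is enhanced with an
    orientation- and scale-matched Gabor filter restricted to those regions and
    the axis offset is refined by a fixed-angle Radon projection; the tip is
    located from window-averaged intensity profiles along the axis (step
    detection on the Doppler profile, derivative refinement on the B-mode
    profile). Includes a seeded synthetic speckle phantom generator with known
    needle geometry, the corresponding evaluation metrics (axis, angle and tip
    errors, failure rate) and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
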