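Package: respitrack
Title: Marker-Based Optical Tracking of Respiratory Motion with a Digital
    Thorax Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Video-based monitoring of respiratory surface motion for
    radiotherapy gating. Detects high-contrast fiducial markers in image
    sequences, initializes trackable corner points with the Shi-Tomasi
    minimum-eigenvalue detector, follows them with pyramidal Lucas-Kanade
    optical flow at sub-pixel resolution, converts pixel trajectories to
    millimetres in anatomical axes, and raises amplitude-gating alerts.
    Ships a digital stand-in for a stepper-driven mechanical thorax
    phantom (modified-sine anteroposterior motion with respiratory
    pauses) that renders synthetic marker videos with frame-exact ground
    truth, so tracking accuracy, sine-fit quality and failure behaviour
    can be validated end to end without hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
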