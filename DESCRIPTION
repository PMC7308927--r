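Package: psm3d
Title: Probe Sector Matching for Freehand 3D Ultrasound Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs a 3D target from tracked freehand 2D ultrasound
    frames by probe sector matching: candidate image planes through an axis
    around the imaging target are precomputed into a sector database, each
    acquired frame is matched to a database plane with a three-point
    dual-space form of the 3D Hough transform, echo depths are compensated
    for surface squeeze (pressure feedback), surface elevation (pose
    feedback) and transmission-medium changes (calibrated echo-time
    offsets), and the compensated pixels are placed into the matched plane.
    Includes a seeded ring-phantom acquisition simulator, plane-detection by
    an accumulator-based 3D Hough transform, evaluation metrics, file
    round-tripping (PNG frame stacks, JSON sector databases, CSV pose
    streams, ASCII PLY point clouds) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    pracma,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
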