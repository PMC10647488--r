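Package: hydromocap
Title: Low-Cost Multi-Camera Underwater Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marker-based three-dimensional underwater motion
    capture with an array of synchronized consumer cameras. Implements
    planar-checkerboard intrinsic and stereo calibration, event-based
    camera synchronization from luminance time series, two-view DLT
    triangulation, rigid unification of camera-pair coordinate frames
    into a global pool frame, equine joint-angle and range-of-motion
    kinematics, and a checkerboard-based reconstruction-error protocol.
    A seeded synthetic-scene generator emulates a six-camera poolside
    rig, checkerboard sweeps and an articulated swimming limb so the
    whole pipeline can be exercised and validated without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
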