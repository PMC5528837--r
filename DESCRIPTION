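Package: skimu
Title: Joint Kinematics from Body-Worn Inertial Sensors in Alpine Skiing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes 3D knee, hip, and trunk joint angles from body-worn
    inertial measurement units (IMUs) during alpine skiing. Implements a
    functional sensor-to-segment calibration built from four field-executable
    movements (squats, trunk rotations, hip ab/adductions, upright standing),
    quaternion strap-down orientation tracking, and a two-pass joint-drift
    correction that translates accelerations of adjacent sensors to their
    shared joint and treats any orientation mismatch between them as drift; a
    dedicated second pass removes heading (azimuth) drift, which is
    unobservable from gravity alone. Joint angles follow the Grood-Suntay
    joint coordinate system. A rigid-body kinematic-chain simulator with known
    ground truth, validation statistics (calibration dispersion,
    repeatability, coefficient of multiple correlation,
    accuracy/precision/correlation), CSV/YAML/JSON interfaces, and a
    command-line entry point are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
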