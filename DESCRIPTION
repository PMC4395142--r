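Package: armvib
Title: Simulation and Analysis of Hand-Vibration Damping in a Planar Three-Link Arm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to study how a seated human dampens hand vibrations when the
    shoulder is oscillated horizontally. Implements the rigid-body dynamics of a
    three-link arm (upper arm, forearm, hand) moving in the sagittal plane on a
    translating base, two equilibrium-point torque controllers (passive
    suppression via joint stiffness with gravity compensation, and active
    suppression via a skyhook virtual damper attached to the hand), a
    fixed-step fourth-order Runge-Kutta simulator, and the kinematic evaluation
    pipeline used to compare controllers: zero-phase Butterworth filtering,
    third-difference jerk, steady-state cycle averaging, mean sum of squared
    jerk per arm part, and hand-trajectory amplitude. A synthetic marker-data
    generator emulates optical motion-capture recordings so the analysis
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
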