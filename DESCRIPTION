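Package: posturefb
Title: Two-Link Stance Dynamics with Delayed Postural Control and
    Vibrotactile Biofeedback Torques
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates human bipedal stance as a three-dimensional two-link
    inverted pendulum (legs and head-arms-trunk, spherical ankle and hip
    joints, locked knees) standing on a horizontally translating platform.
    Posture is stabilised by independent delayed full-state-feedback
    controllers in the sagittal and coronal planes; vibrotactile biofeedback
    of torso tilt is modelled as an additional joint torque that relaxes with
    first-order dynamics toward row- and direction-dependent targets set by a
    tactor display. Includes anthropometric parameter derivation from subject
    height and mass, trapezoidal support-surface perturbation profiles,
    centre-of-pressure output, trajectory validation metrics (windowed
    average error and normalised cross-correlation), and a two-stage
    parameter-fitting procedure (grid sweep followed by coordinate-wise
    perpendicular search) for controller gains and biofeedback parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
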