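Package: gazecal
Title: Geometry-Aware Eye-Tracker Calibration for Planar Workspaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calibrates raw two-channel eye-tracker voltages to gaze
    positions on a horizontal planar workspace viewed from above,
    compensating the perspective nonlinearity of the rig geometry.
    Provides bivariate polynomial calibration surfaces (orders 2-4)
    fitted after biharmonic-spline regridding of sparse voltage-space
    anchors, constant-offset drift correction from a centre-target
    fixation, conversion of planar gaze to eye-centred vectors and
    polar visual angles, a validation battery (median-distance
    accuracy, interquartile and sample-to-sample RMS precision,
    rank-sum distribution comparisons, discriminability tests), and a
    servo-controlled artificial-eye simulator so every stage can be
    exercised without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
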