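## Shared fixtures: the default rig, forward models, and a noise-free
## calibration built once for the whole suite.

fix_geom <- rigGeometry()                       # 20 x 9 cm, eye (0,30,-25)
fix_fm <- pinholeForwardModel()
fix_grid <- calibrationGrid(fix_geom)           # 5 x 5 over the work area

fix_calib_session <- simulateFixationSession(
  fix_grid, fix_fm, noiseModel(), fix_geom, seed = 101L)
fix_model4 <- calibrate(fix_calib_session, order = 4)

## uniformly random in-area targets under a local seed
random_targets <- function(n, geometry, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  wa <- geometry@workAreaCm
  cbind(runif(n, -wa[1] / 2, wa[1] / 2), runif(n, -wa[2] / 2, wa[2] / 2))
}

## random unit-ish gaze vectors pointing into the lower hemisphere
random_gaze_vectors <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cbind(rnorm(n), rnorm(n) + 2, rnorm(n) - 2)
}

## anchors whose cm values are an exact affine map of their voltages
affine_anchors <- function(a = 3, b = 0.5, d = -0.2, e = 2, n = 5) {
  g <- expand.grid(xv_volts = seq(-2, 2, length.out = n),
                   yv_volts = seq(-1.5, 1.5, length.out = n))
  g$target_x_cm <- 1 + a * g$xv_volts + b * g$yv_volts
  g$target_y_cm <- -0.5 + d * g$xv_volts + e * g$yv_volts
  g
}
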