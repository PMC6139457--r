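test_that("drift estimation follows its defining difference", {
  v <- matrix(rep(c(1.5, -0.7), each = 10), ncol = 2)
  d0 <- estimateDrift(v, v)
  expect_equal(driftVoltage(d0), c(0, 0))
  shifted <- sweep(v, 2, -c(0.3, -0.1))          # current = calib + (0.3,-0.1)
  d <- estimateDrift(shifted, v)
  expect_equal(driftVoltage(d), c(-0.3, 0.1))
  expect_error(estimateDrift(v[0, , drop = FALSE], v), "empty")
})

test_that("drift recovered from a simulated head shift matches ground truth", {
  dv <- c(0.25, -0.15)
  nz <- noiseModel(voltageNoiseV = 0.02, headShiftV = dv)
  center <- fix_grid[13, , drop = FALSE]         # grid centre target
  calEpoch <- simulateFixationSession(center, fix_fm, noiseModel(voltageNoiseV = 0.02),
                                      fix_geom, nRepeats = 3, seed = 201)
  nowEpoch <- simulateFixationSession(center, fix_fm, nz, fix_geom,
                                      nRepeats = 3, seed = 202)
  d <- estimateDrift(as.matrix(sessionSamples(nowEpoch)[, c("xv_volts", "yv_volts")]),
                     as.matrix(sessionSamples(calEpoch)[, c("xv_volts", "yv_volts")]))
  sem <- 0.02 / sqrt(300)
  expect_true(all(abs(driftVoltage(d) - (-dv)) < 4 * sem))
})

test_that("drift application is the identity at zero and exactly invertible", {
  ses <- simulateFixationSession(fix_grid[1:4, ], fix_fm, noiseModel(),
                                 fix_geom, seed = 203)
  zero <- new("DriftOffset", dv = c(0, 0), estimatedAt = 0,
              centerTarget = c(0, 0), nSamples = 1L)
  expect_identical(sessionSamples(applyDrift(ses, zero)),
                   sessionSamples(ses))
  d <- new("DriftOffset", dv = c(0.25, -0.5), estimatedAt = 0,
           centerTarget = c(0, 0), nSamples = 1L)
  inv <- new("DriftOffset", dv = -d@dv, estimatedAt = 0,
             centerTarget = c(0, 0), nSamples = 1L)
  back <- applyDrift(applyDrift(ses, d), inv)
  expect_equal(sessionSamples(back)$xv_volts, sessionSamples(ses)$xv_volts)
})

test_that("noise-free drift correction restores the unshifted reconstruction", {
  dv <- c(0.25, -0.5)                            # dyadic: exact float algebra
  ses <- simulateFixationSession(fix_grid, fix_fm, noiseModel(), fix_geom,
                                 seed = 205)
  shifted <- applyHeadShift(ses, dv)
  center <- fix_grid[13, , drop = FALSE]
  calCenter <- forwardVoltages(fix_fm, center, fix_geom)
  nowCenter <- calCenter + rep(dv, each = 1)
  d <- estimateDrift(nowCenter, calCenter)
  expect_identical(driftVoltage(d), -dv)
  recShifted <- reconstructSession(shifted, fix_model4, drift = d)
  recClean <- reconstructSession(ses, fix_model4)
  expect_identical(recShifted$x_cm, recClean$x_cm)
  expect_identical(recShifted$y_cm, recClean$y_cm)
})

test_that("voltage-to-gaze evaluation honours the affine special case", {
  lin <- polynomialInverseModel(order = 4L,
                                coeffsX = c(c_10 = 4), coeffsY = c(c_01 = 2.5))
  ses <- simulateFixationSession(fix_grid, lin, noiseModel(), fix_geom,
                                 seed = 207)
  m <- calibrate(ses, order = 2, fitOn = "anchors")
  V <- matrix(c(0.5, -1.2), ncol = 2)
  gz <- voltagesToGaze(V, m)
  expect_equal(gz$x_cm, 4 * 0.5, tolerance = 1e-8)
  expect_equal(gz$y_cm, 2.5 * -1.2, tolerance = 1e-8)
})

test_that("anchor voltages reconstruct their targets within the fit residual", {
  anchors <- averageAnchors(fix_calib_session)
  gz <- voltagesToGaze(as.matrix(anchors[, c("xv_volts", "yv_volts")]),
                       fix_model4)
  r <- fitResiduals(fix_model4)
  tol <- max(abs(c(r$res_x_cm, r$res_y_cm))) + 1e-9
  expect_true(all(abs(gz$x_cm - anchors$target_x_cm) <= tol))
  expect_true(all(abs(gz$y_cm - anchors$target_y_cm) <= tol))
})

test_that("extrapolation and invalid samples are flagged, not fatal", {
  box <- validVoltageBox(fix_model4)
  out <- voltagesToGaze(c(box[1, 2] + 1, 0), fix_model4)
  expect_true(out$extrapolated)
  expect_true(out$valid)
  nf <- voltagesToGaze(rbind(c(NA, 0), c(1, 1)), fix_model4)
  expect_false(nf$valid[1])
  expect_true(is.na(nf$x_cm[1]))
  expect_true(nf$valid[2])
})

test_that("streaming and batch evaluation agree bit-exactly", {
  V <- as.matrix(sessionSamples(fix_calib_session)[1:200, c("xv_volts", "yv_volts")])
  batch <- voltagesToGaze(V, fix_model4)
  oneByOne <- t(vapply(seq_len(nrow(V)), function(i) {
    g <- voltagesToGaze(V[i, ], fix_model4)
    c(g$x_cm, g$y_cm)
  }, numeric(2)))
  expect_identical(batch$x_cm, oneByOne[, 1])
  expect_identical(batch$y_cm, oneByOne[, 2])
})

test_that("reconstruction is continuous over the valid voltage box", {
  box <- validVoltageBox(fix_model4)
  set.seed(211)
  V <- cbind(runif(500, box[1, 1], box[1, 2]),
             runif(500, box[2, 1], box[2, 2]))
  dV <- matrix(runif(1000, -5e-4, 5e-4), ncol = 2)   # < 1 mV steps
  g1 <- voltagesToGaze(V, fix_model4)
  g2 <- voltagesToGaze(V + dV, fix_model4)
  stepCm <- sqrt((g1$x_cm - g2$x_cm)^2 + (g1$y_cm - g2$y_cm)^2)
  expect_lt(max(stepCm), 0.1)
})

test_that("gaze-to-angle conversion matches explicit 3D constructions", {
  g <- fix_geom
  o <- g@screenOriginInEyeFrame
  below <- c(-o[1], -o[2])                       # point directly under the eye
  ang <- gazeToAngles(below, g)
  expect_equal(ang$phi_deg, -90)
  expect_equal(ang$rho_cm, abs(o[3]))
  p <- random_targets(20, g, seed = 213)
  ang <- gazeToAngles(p, g)
  u <- screenToEyeFrame(p, g)
  expect_equal(ang$rho_cm, sqrt(rowSums(u^2)))   # rho = eye-to-point distance
  ## pairwise angular distances from angles match the vector route
  v1 <- polarToVector(ang$rho_cm, ang$theta_deg, ang$phi_deg)
  expect_equal(angularDistance(v1, u), rep(0, 20), tolerance = 1e-9)
})
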