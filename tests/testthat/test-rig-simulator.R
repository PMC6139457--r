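test_that("calibration grid spans the work area in row-major order", {
  grid <- calibrationGrid(rigGeometry(workAreaCm = c(20, 9)))
  expect_equal(nrow(grid), 25)
  expect_equal(nrow(unique(grid)), 25)
  ## corners at +/-10, +/-4.5 relative to the centre
  expect_equal(unname(grid[1, ]), c(-10, -4.5))
  expect_equal(unname(grid[25, ]), c(10, 4.5))
  ## x varies fastest
  expect_equal(grid[2, 2], grid[1, 2])
  g22 <- calibrationGrid(c(20, 9), nRows = 2, nCols = 2)
  expect_equal(sort(g22[, 1]), c(-10, -10, 10, 10))
  expect_equal(sort(g22[, 2]), c(-4.5, -4.5, 4.5, 4.5))
  expect_error(calibrationGrid(c(0, 9)), "degenerate")
  expect_error(calibrationGrid(c(20, 9), nRows = 1), "at least 2")
})

test_that("a linear forward configuration yields voltages proportional to cm", {
  lin <- polynomialInverseModel(order = 4L,
                                coeffsX = c(c_10 = 4), coeffsY = c(c_01 = 2.5))
  p <- random_targets(20, fix_geom, seed = 51)
  V <- forwardVoltages(lin, p, fix_geom)
  expect_equal(V[, 1], p[, 1] / 4, tolerance = 1e-10)
  expect_equal(V[, 2], p[, 2] / 2.5, tolerance = 1e-10)
})

test_that("pinhole model compresses equal cm steps more at nearer depths", {
  wa <- fix_geom@workAreaCm
  near <- forwardVoltages(fix_fm, rbind(c(-5, -wa[2] / 2), c(5, -wa[2] / 2)),
                          fix_geom)
  far <- forwardVoltages(fix_fm, rbind(c(-5, wa[2] / 2), c(5, wa[2] / 2)),
                         fix_geom)
  dNear <- abs(diff(near[, 1])); dFar <- abs(diff(far[, 1]))
  expect_gt(abs(dNear - dFar), 1e-3)   # perspective: alpha != beta
})

test_that("all 25 grid targets stay inside the voltage range", {
  V <- forwardVoltages(fix_fm, fix_grid, fix_geom)
  expect_false(any(attr(V, "saturated")))
  r <- fix_fm@voltageRangeV
  expect_true(all(V[, 1] >= r[1, 1] & V[, 1] <= r[1, 2]))
  expect_true(all(V[, 2] >= r[2, 1] & V[, 2] <= r[2, 2]))
})

test_that("both voltage channels are strictly monotone along their screen axis", {
  xs <- seq(-10, 10, length.out = 15)
  ys <- seq(-4.5, 4.5, length.out = 15)
  for (y0 in ys) {
    vx <- forwardVoltages(fix_fm, cbind(xs, y0), fix_geom)[, 1]
    expect_true(all(diff(vx) > 0))
  }
  for (x0 in xs) {
    vy <- forwardVoltages(fix_fm, cbind(x0, ys), fix_geom)[, 2]
    expect_true(all(diff(vy) > 0) || all(diff(vy) < 0))
  }
})

test_that("noise-free sessions repeat the forward voltages exactly", {
  ses <- simulateFixationSession(fix_grid[1:3, ], fix_fm, noiseModel(),
                                 fix_geom, nRepeats = 2, seed = 61)
  s <- sessionSamples(ses)
  for (id in unique(s$trial_id)) {
    tr <- s[s$trial_id == id, ]
    V0 <- forwardVoltages(fix_fm, c(tr$target_x_cm[1], tr$target_y_cm[1]),
                          fix_geom)
    expect_equal(tr$xv_volts, rep(V0[1, 1], nrow(tr)), tolerance = 1e-12)
    expect_equal(tr$yv_volts, rep(V0[1, 2], nrow(tr)), tolerance = 1e-12)
  }
  expect_true(all(s$valid))
})

test_that("sessions are bit-identical under a fixed seed", {
  nz <- noiseModel(sampleNoiseDegRMS = 0.05, voltageNoiseV = 0.01,
                   trialScatterDegSD = 0.1, blinkProb = 0.3)
  a <- simulateFixationSession(fix_grid, fix_fm, nz, fix_geom, seed = 71)
  b <- simulateFixationSession(fix_grid, fix_fm, nz, fix_geom, seed = 71)
  expect_identical(sessionSamples(a), sessionSamples(b))
  c2 <- simulateFixationSession(fix_grid, fix_fm, nz, fix_geom, seed = 72)
  expect_false(identical(sessionSamples(a), sessionSamples(c2)))
})

test_that("target presentation order is randomized by the seed", {
  ses <- simulateFixationSession(fix_grid, fix_fm, noiseModel(), fix_geom,
                                 seed = 73)
  s <- sessionSamples(ses)
  firstTargets <- s[!duplicated(s$trial_id), c("target_x_cm", "target_y_cm")]
  ordered <- rbind(fix_grid, fix_grid, fix_grid)
  expect_false(isTRUE(all.equal(as.matrix(firstTargets), ordered,
                                check.attributes = FALSE)))
})

test_that("blink trials carry flagged out-of-range excursions", {
  nz <- noiseModel(blinkProb = 1)
  ses <- simulateFixationSession(fix_grid[1:5, ], fix_fm, nz, fix_geom,
                                 nRepeats = 2, seed = 81)
  s <- sessionSamples(ses)
  for (id in unique(s$trial_id)) {
    tr <- s[s$trial_id == id, ]
    expect_true(any(!tr$valid))
    expect_true(all(tr$xv_volts[!tr$valid] > fix_fm@voltageRangeV[1, 2]))
  }
})

test_that("head shift is additive, invertible, and commutes with the forward model", {
  ses <- simulateFixationSession(fix_grid[1:4, ], fix_fm, noiseModel(),
                                 fix_geom, seed = 91)
  expect_identical(sessionSamples(applyHeadShift(ses, c(0, 0))),
                   sessionSamples(ses))
  dv <- c(0.1, -0.2)
  back <- applyHeadShift(applyHeadShift(ses, dv), -dv)
  expect_equal(sessionSamples(back)$xv_volts, sessionSamples(ses)$xv_volts)
  expect_equal(sessionSamples(back)$yv_volts, sessionSamples(ses)$yv_volts)
  ## simulating with headShiftV equals shifting the clean session
  nzShift <- noiseModel(headShiftV = dv)
  viaNoise <- simulateFixationSession(fix_grid[1:4, ], fix_fm, nzShift,
                                      fix_geom, seed = 91)
  expect_identical(sessionSamples(viaNoise),
                   sessionSamples(applyHeadShift(ses, dv)))
})

test_that("a shifted session is distinguishable from the original at the voltage level", {
  nz <- noiseModel(voltageNoiseV = 0.02)
  ses <- simulateFixationSession(fix_grid[13, , drop = FALSE], fix_fm, nz,
                                 fix_geom, nRepeats = 1, seed = 95)
  v0 <- sessionSamples(ses)$xv_volts
  v1 <- sessionSamples(applyHeadShift(ses, c(0.3, 0)))$xv_volts
  expect_lt(compareDistributions(v0, v1), 1e-4)
})
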