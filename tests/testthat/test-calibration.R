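test_that("sample selection keeps clean trials and strips blink excursions", {
  s <- sessionSamples(fix_calib_session)
  tr <- s[s$trial_id == 1, ]
  sel <- selectSamples(tr)
  expect_equal(nrow(sel$samples), nrow(tr))
  expect_true(sel$report$usable)

  ## inject a sentinel excursion mid-window
  bad <- tr
  ix <- 40:60
  bad$xv_volts[ix] <- 11; bad$yv_volts[ix] <- 11; bad$valid[ix] <- FALSE
  sel <- selectSamples(bad, voltageRange = fix_fm@voltageRangeV)
  expect_equal(nrow(sel$samples), nrow(tr) - length(ix))
  expect_equal(sel$report$n_invalid_flag, length(ix))
  expect_true(all(sel$samples$xv_volts < 11))

  expect_error(selectSamples(tr[0, ]), "empty trial")
})

test_that("outlier rule rejects samples far from the trial median", {
  s <- sessionSamples(fix_calib_session)
  tr <- s[s$trial_id == 2, ]
  tr$xv_volts <- tr$xv_volts + rnorm(nrow(tr), 0, 0.01)  # give MAD support
  tr$xv_volts[5] <- tr$xv_volts[5] + 3                   # a saccade-like jump
  sel <- selectSamples(tr, outlierSD = 5)
  expect_equal(sel$report$n_outlier, 1L)
  expect_equal(nrow(sel$samples), nrow(tr) - 1L)
  expect_lt(max(sel$samples$xv_volts), max(tr$xv_volts))
})

test_that("anchors of a noise-free session equal the forward voltages exactly", {
  anchors <- averageAnchors(fix_calib_session)
  expect_equal(nrow(anchors), 25)
  V <- forwardVoltages(fix_fm, as.matrix(anchors[, c("target_x_cm", "target_y_cm")]),
                       fix_geom)
  expect_equal(anchors$xv_volts, V[, 1], tolerance = 1e-12)
  expect_equal(anchors$yv_volts, V[, 2], tolerance = 1e-12)
})

test_that("a blink-contaminated repeat barely moves the anchor", {
  nz <- noiseModel(voltageNoiseV = 0.01, blinkProb = 0.34)
  ses <- simulateFixationSession(fix_grid, fix_fm, nz, fix_geom, seed = 103)
  anchors <- averageAnchors(ses, voltageRange = fix_fm@voltageRangeV)
  clean <- forwardVoltages(fix_fm,
                           as.matrix(anchors[, c("target_x_cm", "target_y_cm")]),
                           fix_geom)
  ## 4 SEM: 50 simultaneous comparisons need a multiplicity-aware bound
  sem <- 0.01 / sqrt(anchors$n_samples)
  expect_true(all(abs(anchors$xv_volts - clean[, 1]) < 4 * sem))
  expect_true(all(abs(anchors$yv_volts - clean[, 2]) < 4 * sem))
})

test_that("missing target coverage is reported by name", {
  s <- sessionSamples(fix_calib_session)
  drop <- s$target_x_cm == -10 & s$target_y_cm == -4.5
  crippled <- new("FixationSession", samples = s[!drop, ],
                  geometry = fix_geom, rateHz = 1000, provenance = list())
  ## a target whose every trial is unusable must be named, not dropped
  s2 <- sessionSamples(fix_calib_session)
  s2$valid[s2$target_x_cm == -10 & s2$target_y_cm == -4.5] <- FALSE
  broken <- new("FixationSession", samples = s2, geometry = fix_geom,
                rateHz = 1000, provenance = list())
  expect_error(averageAnchors(broken), "-10/-4.5")
  expect_equal(nrow(averageAnchors(crippled)), 24)
})

test_that("biharmonic regrid reproduces affine anchor sets to 1e-8", {
  anc <- affine_anchors()
  mesh <- regridBiharmonic(anc, resolution = 21)
  lat <- as.matrix(expand.grid(mesh@gridXv, mesh@gridYv))
  expect_lt(max(abs(as.vector(mesh@valuesXcm) -
                    (1 + 3 * lat[, 1] + 0.5 * lat[, 2]))), 1e-8)
  expect_lt(max(abs(as.vector(mesh@valuesYcm) -
                    (-0.5 - 0.2 * lat[, 1] + 2 * lat[, 2]))), 1e-8)
})

test_that("biharmonic surface interpolates its anchors and rejects duplicates", {
  anchors <- averageAnchors(fix_calib_session)
  mesh <- regridBiharmonic(anchors)
  at <- meshPredict(mesh, as.matrix(anchors[, c("xv_volts", "yv_volts")]))
  expect_lt(max(abs(at[, 1] - anchors$target_x_cm)), 1e-8)
  expect_lt(max(abs(at[, 2] - anchors$target_y_cm)), 1e-8)

  dup <- rbind(anchors, anchors[3, ])
  expect_error(regridBiharmonic(dup), "duplicate")
  expect_error(regridBiharmonic(anchors[1:4, ]), "at least 6")
})

test_that("an exact quartic inverse is recovered coefficient-perfect", {
  pm <- polynomialInverseModel()
  ses <- simulateFixationSession(fix_grid, pm, noiseModel(), fix_geom,
                                 seed = 107)
  m <- calibrate(ses, order = 4, fitOn = "anchors")
  r <- fitResiduals(m)
  expect_lt(max(abs(c(r$res_x_cm, r$res_y_cm))), 1e-9)
})

test_that("affine data leave higher-order coefficients at zero", {
  anc <- affine_anchors()
  m <- fitPolynomial(anc, order = 2)
  co <- modelCoefficients(m)
  high <- c("c_20", "c_11", "c_02")
  expect_lt(max(abs(co$x[high])), 1e-9)
  expect_lt(max(abs(co$y[high])), 1e-9)
  expect_lt(max(abs(fitResiduals(m)$res_x_cm)), 1e-9)
})

test_that("training RMS residuals are non-increasing in polynomial order", {
  anchors <- averageAnchors(fix_calib_session)
  rms <- vapply(2:4, function(ord) {
    r <- fitResiduals(fitPolynomial(anchors, order = ord))
    sqrt(mean(r$res_x_cm^2 + r$res_y_cm^2))
  }, numeric(1))
  expect_true(all(diff(rms) <= 1e-12))
})

test_that("the fit is permutation-invariant and flags rank deficiency", {
  anchors <- averageAnchors(fix_calib_session)
  m1 <- fitPolynomial(anchors, order = 3)
  set.seed(1); m2 <- fitPolynomial(anchors[sample.int(nrow(anchors)), ],
                                   order = 3)
  expect_equal(modelCoefficients(m1)$x, modelCoefficients(m2)$x,
               tolerance = 1e-9)
  ## collinear voltages cannot support a bivariate surface
  degen <- data.frame(xv_volts = seq(0, 1, length.out = 10),
                      yv_volts = seq(0, 2, length.out = 10),
                      target_x_cm = 1:10, target_y_cm = 1:10)
  expect_error(fitPolynomial(degen, order = 2), "rank")
})

test_that("mesh-fit and anchor-fit models agree closely on clean data", {
  mMesh <- calibrate(fix_calib_session, order = 4, fitOn = "mesh")
  mAnch <- calibrate(fix_calib_session, order = 4, fitOn = "anchors")
  probes <- random_targets(50, fix_geom, seed = 113)
  V <- forwardVoltages(fix_fm, probes, fix_geom)
  gm <- voltagesToGaze(V, mMesh); ga <- voltagesToGaze(V, mAnch)
  expect_lt(max(abs(gm$x_cm - ga$x_cm)), 0.1)
  expect_lt(max(abs(gm$y_cm - ga$y_cm)), 0.1)
})

test_that("order comparison detects corruption and ranks orders sensibly", {
  val <- simulateFixationSession(random_targets(25, fix_geom, seed = 127),
                                 fix_fm, noiseModel(), fix_geom, seed = 128)
  m4 <- fix_model4
  identicalPair <- compareOrders(list(a = m4, b = m4), val)
  expect_equal(identicalPair$pairwise$p_value, 1)
  expect_equal(identicalPair$per_model$mean_error_deg[1],
               identicalPair$per_model$mean_error_deg[2])

  corrupted <- m4
  corrupted@coeffsX["c_11"] <- corrupted@coeffsX["c_11"] + 0.5
  cmp <- compareOrders(list(clean = m4, corrupted = corrupted), val)
  expect_gt(cmp$per_model$mean_error_deg[cmp$per_model$model == "corrupted"],
            cmp$per_model$mean_error_deg[cmp$per_model$model == "clean"])

  ## on anchor fits the truncation error is the only error source, so
  ## the order ladder must be monotone
  models <- lapply(2:4, function(k)
    calibrate(fix_calib_session, order = k, fitOn = "anchors"))
  names(models) <- paste0("order", 2:4)
  ranked <- compareOrders(models, val)
  err <- ranked$per_model$mean_error_deg
  expect_true(all(diff(err) <= 1e-12))
})
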