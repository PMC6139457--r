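## Synthetic rig: servo-controlled artificial eye fixating targets on a
## horizontal display, seen by the tracker through a forward model with
## a perspective (depth-dependent) nonlinearity.

#' Calibration target grid
#'
#' Evenly spaced n x m grid of fixation targets spanning the work area,
#' in row-major order (x varies fastest), centred on the screen-frame
#' origin.  The default reproduces the 25-target 5 x 5 layout whose
#' size is adapted to the work area.
#'
#' @param geometry a [RigGeometry-class] (or a numeric 2-vector of
#'   work-area width/depth in cm).
#' @param nRows,nCols grid dimensions (along depth and width), both
#'   at least 2.
#' @return an (nRows*nCols) x 2 matrix of target positions, cm.
#' @examples
#' calibrationGrid(rigGeometry(workAreaCm = c(20, 9)))[c(1, 25), ]
#' @export
calibrationGrid <- function(geometry, nRows = 5L, nCols = 5L) {
  wa <- if (is(geometry, "RigGeometry")) geometry@workAreaCm
        else as.numeric(geometry)
  if (length(wa) != 2L || any(!is.finite(wa)) || any(wa <= 0))
    stop("degenerate work area")
  if (nRows < 2L || nCols < 2L)
    stop("grid must have at least 2 rows and 2 columns")
  xs <- seq(-wa[1] / 2, wa[1] / 2, length.out = nCols)
  ys <- seq(-wa[2] / 2, wa[2] / 2, length.out = nRows)
  as.matrix(expand.grid(x_cm = xs, y_cm = ys))
}

## ---- forward models ----------------------------------------------------

.clipVoltages <- function(V, model) {
  r <- model@voltageRangeV
  sat <- V[, 1] < r[1, 1] | V[, 1] > r[1, 2] |
         V[, 2] < r[2, 1] | V[, 2] > r[2, 2]
  V[, 1] <- pmin(pmax(V[, 1], r[1, 1]), r[1, 2])
  V[, 2] <- pmin(pmax(V[, 2], r[2, 1]), r[2, 2])
  attr(V, "saturated") <- sat
  V
}

#' @describeIn forwardVoltages pinhole projection of the rotating
#'   eyeball's pupil: the pupil centre lies on the eyeball surface
#'   along the gaze direction and is imaged through a pinhole camera;
#'   image coordinates are scaled by the focal gains.
#' @export
setMethod("forwardVoltages",
  signature(model = "PinholeForwardModel"),
  function(model, points, geometry) {
    p <- .as_points(points, 2L, "points")
    u <- screenToEyeFrame(p, geometry)
    u <- u / sqrt(rowSums(u^2))                # unit gaze direction
    P <- model@eyeballRadiusCm * u             # pupil centre on eyeball
    a <- model@cameraAxis
    e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * a) * a
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(a[2] * e1[3] - a[3] * e1[2],       # a x e1
            a[3] * e1[1] - a[1] * e1[3],
            a[1] * e1[2] - a[2] * e1[1])
    d <- sweep(P, 2, model@cameraPositionCm)   # camera-to-pupil rays
    iz <- d %*% a
    if (any(abs(iz) < 1e-9))
      stop("projection degenerate: gaze ray parallel to the image plane")
    V <- cbind(model@focalGainV[1] * (d %*% e1) / iz + model@voltageOffsetV[1],
               model@focalGainV[2] * (d %*% e2) / iz + model@voltageOffsetV[2])
    .clipVoltages(V, model)
  })

#' @describeIn forwardVoltages Newton inversion of the model's exact
#'   polynomial voltage-to-cm inverse.
#' @export
setMethod("forwardVoltages",
  signature(model = "PolynomialInverseModel"),
  function(model, points, geometry) {
    p <- .as_points(points, 2L, "points")
    ## linear part of the inverse provides the starting point
    A <- rbind(c(.coefOr0(model@coeffsX, "c_10"), .coefOr0(model@coeffsX, "c_01")),
               c(.coefOr0(model@coeffsY, "c_10"), .coefOr0(model@coeffsY, "c_01")))
    b <- c(.coefOr0(model@coeffsX, "c_00"), .coefOr0(model@coeffsY, "c_00"))
    V <- t(solve(A, t(sweep(p, 2, b))))
    resid <- function(V) cbind(.polyEval(model@coeffsX, V[, 1], V[, 2]) - p[, 1],
                               .polyEval(model@coeffsY, V[, 1], V[, 2]) - p[, 2])
    f <- resid(V)
    for (it in 1:200) {
      if (max(abs(f)) < 1e-13) break
      gx <- .polyGrad(model@coeffsX, V[, 1], V[, 2])
      gy <- .polyGrad(model@coeffsY, V[, 1], V[, 2])
      det <- gx[, 1] * gy[, 2] - gx[, 2] * gy[, 1]
      if (any(abs(det) < 1e-12))
        stop("projection degenerate: singular Jacobian in forward inversion")
      step <- cbind(( gy[, 2] * f[, 1] - gx[, 2] * f[, 2]) / det,
                    (-gy[, 1] * f[, 1] + gx[, 1] * f[, 2]) / det)
      ## damped update: halve any row's step while its residual worsens
      lam <- rep(1, nrow(V))
      for (h in 1:30) {
        Vn <- V - step * lam
        fn <- resid(Vn)
        worse <- rowSums(abs(fn)) > rowSums(abs(f)) & lam > 1e-6
        if (!any(worse)) break
        lam[worse] <- lam[worse] / 2
      }
      V <- V - step * lam
      f <- resid(V)
    }
    if (max(abs(f)) > 1e-8)
      stop("forward inversion did not converge: the inverse polynomial ",
           "may not be monotone over the requested points")
    V <- sweep(V, 2, -model@voltageOffsetV)
    .clipVoltages(V, model)
  })

.coefOr0 <- function(coeffs, nm) if (nm %in% names(coeffs)) coeffs[[nm]] else 0

## ---- session simulation ------------------------------------------------

## Deviate a screen point by (ah, av) degrees of visual angle along the
## horizontal/vertical tangent axes of its gaze direction, then
## re-intersect the deviated ray with the display plane.  Isotropic in
## the tangent plane, so a deviation of (ah, av) subtends
## sqrt(ah^2 + av^2) degrees regardless of where the target sits.
.perturbOnScreen <- function(p, ah, av, geometry) {
  u <- screenToEyeFrame(p, geometry)
  d <- u / sqrt(rowSums(u^2))
  ## horizontal tangent: z-hat x d, normalized (targets are off-nadir)
  eh <- cbind(-d[, 2], d[, 1], 0)
  nh <- sqrt(rowSums(eh^2))
  if (any(nh < 1e-12))
    stop("gaze at nadir: horizontal tangent undefined")
  eh <- eh / nh
  ev <- cbind(d[, 2] * eh[, 3] - d[, 3] * eh[, 2],   # d x eh
              d[, 3] * eh[, 1] - d[, 1] * eh[, 3],
              d[, 1] * eh[, 2] - d[, 2] * eh[, 1])
  dnew <- d + .rad(ah) * eh + .rad(av) * ev
  eyeFrameToScreen(dnew, geometry, project = TRUE)
}

#' Simulate a fixation session with the artificial eye
#'
#' For each target and repeat, the artificial eye fixates the target
#' for \code{windowMs} at \code{rateHz}: the true gaze is the target
#' plus a per-trial fixational offset (degrees of visual angle along
#' the horizontal/vertical tangent axes of the gaze direction), each
#' sample adds angular jitter on the same axes, and the perturbed gaze
#' is pushed through the forward model to volts, plus sensor noise and
#' any constant head-shift offset.  With \code{blinkProb > 0}, affected trials carry a
#' contiguous excursion of saturated out-of-range samples flagged
#' invalid.  Trials are presented in a random sequence; everything is
#' deterministic given \code{seed}.
#'
#' @param targets n x 2 matrix of target positions (cm).
#' @param model a [TrackerForwardModel-class].
#' @param noise a [NoiseModel-class].
#' @param geometry a [RigGeometry-class].
#' @param nRepeats fixations per target (at least 3 recommended).
#' @param windowMs recording window per fixation, ms.
#' @param rateHz sampling rate, Hz.
#' @param seed integer RNG seed; required.
#' @return a [FixationSession-class].
#' @export
simulateFixationSession <- function(targets, model, noise, geometry,
                                    nRepeats = 3L, windowMs = 100,
                                    rateHz = 1000, seed) {
  targets <- .as_points(targets, 2L, "targets")
  if (nrow(targets) == 0L) stop("empty target list")
  if (nRepeats < 1L) stop("nRepeats must be at least 1")
  if (missing(seed)) stop("a seed is required for reproducibility")
  nSamp <- max(1L, round(windowMs * rateHz / 1000))
  dt <- 1000 / rateHz

  runif(1)  # ensure .Random.seed exists before we capture it
  oldSeed <- .Random.seed
  on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)

  sched <- expand.grid(target = seq_len(nrow(targets)),
                       rep = seq_len(nRepeats))
  sched <- sched[sample.int(nrow(sched)), , drop = FALSE]  # random sequence

  axSD <- noise@sampleNoiseDegRMS / sqrt(2)
  out <- vector("list", nrow(sched))
  for (k in seq_len(nrow(sched))) {
    tgt <- targets[sched$target[k], ]
    scat <- rnorm(2, 0, noise@trialScatterDegSD)
    jit <- matrix(rnorm(2 * nSamp, 0, axSD), nSamp, 2)
    gaze <- .perturbOnScreen(matrix(tgt, nSamp, 2, byrow = TRUE),
                             scat[1] + jit[, 1], scat[2] + jit[, 2],
                             geometry)
    V <- forwardVoltages(model, gaze, geometry)
    V <- V + matrix(rnorm(2 * nSamp, 0, noise@voltageNoiseV), nSamp, 2)
    V <- sweep(V, 2, -noise@headShiftV)
    valid <- rep(TRUE, nSamp)
    if (noise@blinkProb > 0 && runif(1) < noise@blinkProb) {
      len <- max(1L, floor(nSamp * 0.3))
      start <- sample.int(nSamp - len + 1L, 1L)
      ix <- start:(start + len - 1L)
      V[ix, 1] <- model@voltageRangeV[1, 2] + 1   # sentinel excursion
      V[ix, 2] <- model@voltageRangeV[2, 2] + 1
      valid[ix] <- FALSE
    }
    out[[k]] <- data.frame(
      trial_id = k,
      target_x_cm = tgt[1], target_y_cm = tgt[2],
      t_ms = (k - 1) * windowMs + (seq_len(nSamp) - 1) * dt,
      xv_volts = V[, 1], yv_volts = V[, 2], valid = valid)
  }
  new("FixationSession",
      samples = do.call(rbind, out),
      geometry = geometry, rateHz = rateHz,
      provenance = list(
        generator = "simulateFixationSession",
        forward_model = class(model)[1],
        noise = list(sample_noise_deg_rms = noise@sampleNoiseDegRMS,
                     voltage_noise_v = noise@voltageNoiseV,
                     trial_scatter_deg_sd = noise@trialScatterDegSD,
                     head_shift_v = noise@headShiftV,
                     blink_prob = noise@blinkProb),
        seed = seed, n_repeats = nRepeats,
        window_ms = windowMs, rate_hz = rateHz,
        head_shifts = list()))
}

#' @describeIn applyHeadShift shift every sample of a session.
#' @export
setMethod("applyHeadShift",
  signature(x = "FixationSession"),
  function(x, dv) {
    dv <- as.numeric(dv)
    if (length(dv) != 2L || !all(is.finite(dv)))
      stop("dv must be a finite 2-vector of volts")
    x@samples$xv_volts <- x@samples$xv_volts + dv[1]
    x@samples$yv_volts <- x@samples$yv_volts + dv[2]
    x@provenance$head_shifts <-
      c(x@provenance$head_shifts, list(dv))
    x
  })

#' @describeIn applyHeadShift shift a plain n x 2 voltage matrix.
#' @export
setMethod("applyHeadShift",
  signature(x = "matrix"),
  function(x, dv) sweep(x, 2, -as.numeric(dv)))

## ---- accessors ---------------------------------------------------------

#' Accessors for FixationSession objects
#'
#' @param x a [FixationSession-class].
#' @return \code{sessionSamples}: the per-sample data.frame;
#'   \code{sessionGeometry}: the [RigGeometry-class];
#'   \code{sessionRate}: the sampling rate (Hz);
#'   \code{sessionProvenance}: the provenance list.
#' @name sessionSamples
#' @export
setMethod("sessionSamples", "FixationSession", function(x) x@samples)

#' @rdname sessionSamples
#' @export
setMethod("sessionGeometry", "FixationSession", function(x) x@geometry)

#' @rdname sessionSamples
#' @export
setMethod("sessionRate", "FixationSession", function(x) x@rateHz)

#' @rdname sessionSamples
#' @export
setMethod("sessionProvenance", "FixationSession", function(x) x@provenance)

setMethod("show", "FixationSession", function(object) {
  s <- object@samples
  cat(sprintf("FixationSession: %d trials, %d samples at %g Hz\n",
              length(unique(s$trial_id)), nrow(s), object@rateHz))
  tg <- unique(s[, c("target_x_cm", "target_y_cm")])
  cat(sprintf("  %d distinct targets on a %g x %g cm work area\n",
              nrow(tg), object@geometry@workAreaCm[1],
              object@geometry@workAreaCm[2]))
  if (!is.null(object@provenance$seed))
    cat(sprintf("  simulated (seed %s)\n", object@provenance$seed))
})

setMethod("show", "RigGeometry", function(object) {
  o <- object@screenOriginInEyeFrame
  cat(sprintf("RigGeometry: work area %g x %g cm, refresh %g Hz\n",
              object@workAreaCm[1], object@workAreaCm[2], object@refreshHz))
  cat(sprintf("  screen origin in eye frame: (%g, %g, %g) cm\n",
              o[1], o[2], o[3]))
  cat(sprintf("  elevation convention: %s\n", object@elevationConvention))
})
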