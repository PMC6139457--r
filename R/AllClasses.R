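#' @import methods
NULL

#' Rig geometry: how the screen frame sits in the eye-centred frame
#'
#' A \code{RigGeometry} ties together the two reference frames of an
#' eye-hand rig with a horizontal display viewed from above: the planar
#' screen frame (centimetres, origin at the work-area centre, x to the
#' participant's right, y increasing away from the body) and the
#' eye-centred 3D frame (X' right, Y' ahead, Z' up, origin at the centre
#' of the eyeball).  The display plane lies below the eye, so the third
#' component of \code{screenOriginInEyeFrame} is negative.
#'
#' @slot screenOriginInEyeFrame numeric(3); coordinates (cm) of the
#'   screen-frame origin expressed in the eye-centred frame.
#' @slot workAreaCm numeric(2); width and depth (cm) of the rectangular
#'   work area, centred on the screen-frame origin.
#' @slot refreshHz scalar; display refresh rate in Hz.
#' @slot screenExtentCm scalar; vertical extent (cm) of the displayed
#'   image swept by one refresh, used by the space--time latency model.
#' @slot referenceSpots 2x2 matrix; two reference screen points (cm),
#'   rows are points, mirroring a two-photoresistor latency measurement.
#' @slot elevationConvention either \code{"from-horizontal"} (elevation
#'   phi measured from the X'Y' plane, negative downward; the default)
#'   or \code{"from-vertical"} (polar angle measured from +Z').
#'
#' @seealso [rigGeometry()] for the user constructor.
#' @export
setClass("RigGeometry",
  representation(
    screenOriginInEyeFrame = "numeric",
    workAreaCm             = "numeric",
    refreshHz              = "numeric",
    screenExtentCm         = "numeric",
    referenceSpots         = "matrix",
    elevationConvention    = "character"
  )
)

setValidity("RigGeometry", function(object) {
  msg <- character()
  o <- object@screenOriginInEyeFrame
  if (length(o) != 3L || !all(is.finite(o)))
    msg <- c(msg, "screenOriginInEyeFrame must be a finite 3-vector")
  else if (o[3] >= 0)
    msg <- c(msg, "screen plane must lie below the eye (o_z < 0)")
  wa <- object@workAreaCm
  if (length(wa) != 2L || !all(is.finite(wa)) || any(wa <= 0))
    msg <- c(msg, "workAreaCm must be two strictly positive extents")
  if (length(object@refreshHz) != 1L || !is.finite(object@refreshHz) ||
      object@refreshHz <= 0)
    msg <- c(msg, "refreshHz must be a positive scalar")
  if (length(object@screenExtentCm) != 1L || object@screenExtentCm <= 0)
    msg <- c(msg, "screenExtentCm must be a positive scalar")
  if (!identical(dim(object@referenceSpots), c(2L, 2L)))
    msg <- c(msg, "referenceSpots must be a 2x2 matrix (two screen points)")
  if (!object@elevationConvention %in% c("from-horizontal", "from-vertical"))
    msg <- c(msg, "elevationConvention must be 'from-horizontal' or 'from-vertical'")
  if (length(msg)) msg else TRUE
})

#' Forward models of the eye tracker (screen cm to raw volts)
#'
#' \code{TrackerForwardModel} is the virtual parent of the simulator's
#' forward maps \code{X_V = f(X_cm, Y_cm)}, \code{Y_V = g(X_cm, Y_cm)}.
#' Two concrete models are provided: [PinholeForwardModel-class], a
#' mechanistic pinhole-camera projection of a rotating eyeball's pupil
#' (the default, reproducing the depth-dependent perspective
#' compression of a horizontal display), and
#' [PolynomialInverseModel-class], an analytically invertible model
#' whose voltage-to-cm inverse is an exact bivariate polynomial (used
#' to exercise the calibration round trip).
#'
#' @export
setClass("TrackerForwardModel", representation("VIRTUAL",
  voltageOffsetV = "numeric",
  voltageRangeV  = "matrix"   # 2x2: rows = channels, cols = lower/upper
))

setValidity("TrackerForwardModel", function(object) {
  msg <- character()
  if (length(object@voltageOffsetV) != 2L || !all(is.finite(object@voltageOffsetV)))
    msg <- c(msg, "voltageOffsetV must be a finite 2-vector")
  r <- object@voltageRangeV
  if (!identical(dim(r), c(2L, 2L)) || any(r[, 1] >= r[, 2]))
    msg <- c(msg, "voltageRangeV must be 2x2 with lower < upper per channel")
  if (length(msg)) msg else TRUE
})

#' Pinhole-camera forward model of the artificial eye
#'
#' Mechanistic stand-in for the servo-controlled artificial eye viewed
#' by the tracker camera: the pupil centre sits on the eyeball surface
#' along the gaze direction, is projected through a pinhole at
#' \code{cameraPositionCm}, and the two image coordinates are scaled to
#' volts.  Eyeball rotation plus the oblique viewing geometry produce
#' the characteristic depth-dependent compression of the voltage grid.
#'
#' @slot eyeballRadiusCm pupil orbit radius (cm).
#' @slot cameraPositionCm pinhole position in the eye-centred frame (cm).
#' @slot cameraAxis unit optical axis; defaults to pointing from the
#'   camera at the eyeball centre.
#' @slot focalGainV volts per unit image coordinate, one per channel.
#' @export
setClass("PinholeForwardModel", contains = "TrackerForwardModel",
  representation(
    eyeballRadiusCm  = "numeric",
    cameraPositionCm = "numeric",
    cameraAxis       = "numeric",
    focalGainV       = "numeric"
  )
)

setValidity("PinholeForwardModel", function(object) {
  msg <- character()
  if (object@eyeballRadiusCm <= 0)
    msg <- c(msg, "eyeballRadiusCm must be positive")
  if (sqrt(sum(object@cameraPositionCm^2)) <= object@eyeballRadiusCm)
    msg <- c(msg, "camera must lie outside the eyeball")
  if (abs(sqrt(sum(object@cameraAxis^2)) - 1) > 1e-8)
    msg <- c(msg, "cameraAxis must be a unit vector")
  if (any(object@focalGainV == 0) || length(object@focalGainV) != 2L)
    msg <- c(msg, "focalGainV must be two nonzero gains")
  if (length(msg)) msg else TRUE
})

#' Analytically invertible forward model (polynomial inverse)
#'
#' A forward map defined implicitly by its inverse: the voltage-to-cm
#' mapping is an exact bivariate polynomial pair
#' \code{x_cm = P_x(X_V, Y_V)}, \code{y_cm = P_y(X_V, Y_V)} and the
#' forward direction is obtained by Newton iteration.  Because the
#' inverse is a polynomial of known order, a calibration of that order
#' must recover it to numerical precision; this model exists to make
#' that round trip testable.
#'
#' @slot order polynomial total degree of the inverse.
#' @slot coeffsX,coeffsY named coefficient vectors (names \code{c_ij}
#'   for the monomial \code{XV^i * YV^j}).
#' @export
setClass("PolynomialInverseModel", contains = "TrackerForwardModel",
  representation(
    order   = "integer",
    coeffsX = "numeric",
    coeffsY = "numeric"
  )
)

#' Noise model for simulated fixation sessions
#'
#' Parameterizes every stochastic ingredient of a simulated recording:
#' per-sample angular jitter of the gaze direction (mapped through the
#' forward model, so it inherits the rig's nonlinearity), additive
#' sensor noise on the voltage channels, a per-trial fixational offset,
#' an optional constant head-shift voltage offset, and a per-trial
#' blink probability.
#'
#' @slot sampleNoiseDegRMS RMS of the per-sample angular deviation
#'   magnitude (degrees); each of the two tangent-plane axes receives
#'   SD = RMS/sqrt(2).
#' @slot voltageNoiseV additive white sensor noise SD (volts/channel).
#' @slot trialScatterDegSD per-trial fixation offset SD per
#'   tangent-plane axis (degrees of visual angle).
#' @slot headShiftV constant voltage offset (volts), emulating a head
#'   displacement relative to the camera.
#' @slot blinkProb probability that a trial contains a blink excursion.
#' @export
setClass("NoiseModel",
  representation(
    sampleNoiseDegRMS = "numeric",
    voltageNoiseV     = "numeric",
    trialScatterDegSD = "numeric",
    headShiftV        = "numeric",
    blinkProb         = "numeric"
  )
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@sampleNoiseDegRMS < 0 || object@voltageNoiseV < 0 ||
      object@trialScatterDegSD < 0)
    msg <- c(msg, "noise SDs must be non-negative")
  if (length(object@headShiftV) != 2L || !all(is.finite(object@headShiftV)))
    msg <- c(msg, "headShiftV must be a finite 2-vector")
  if (object@blinkProb < 0 || object@blinkProb > 1)
    msg <- c(msg, "blinkProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A recorded (or simulated) fixation session
#'
#' Container for the per-sample records of a calibration or validation
#' session: one row per 1-kHz sample, grouped into trials, each trial
#' tied to a known target on the work area.  The \code{samples} slot is
#' a data.frame with columns \code{trial_id}, \code{target_x_cm},
#' \code{target_y_cm}, \code{t_ms}, \code{xv_volts}, \code{yv_volts},
#' \code{valid}.
#'
#' @slot samples per-sample data.frame (see above).
#' @slot geometry the [RigGeometry-class] of the recording.
#' @slot rateHz sampling rate (Hz).
#' @slot provenance list of generation parameters (forward model,
#'   noise, seed, any head shift applied).
#' @export
setClass("FixationSession",
  representation(
    samples    = "data.frame",
    geometry   = "RigGeometry",
    rateHz     = "numeric",
    provenance = "list"
  )
)

.session_cols <- c("trial_id", "target_x_cm", "target_y_cm", "t_ms",
                   "xv_volts", "yv_volts", "valid")

setValidity("FixationSession", function(object) {
  msg <- character()
  s <- object@samples
  if (!all(.session_cols %in% names(s)))
    msg <- c(msg, paste("samples must have columns:",
                        paste(.session_cols, collapse = ", ")))
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a positive scalar")
  if (nrow(s) > 0 && all(.session_cols %in% names(s))) {
    bad <- vapply(split(s$t_ms, s$trial_id),
                  function(t) any(diff(t) <= 0), logical(1))
    if (any(bad))
      msg <- c(msg, paste("timestamps not strictly increasing in trial(s):",
                          paste(names(bad)[bad], collapse = ", ")))
    g <- object@geometry
    half <- g@workAreaCm / 2
    tg <- unique(s[, c("target_x_cm", "target_y_cm")])
    out <- abs(tg$target_x_cm) > half[1] + 1e-9 |
           abs(tg$target_y_cm) > half[2] + 1e-9
    if (any(out))
      msg <- c(msg, "some trial targets lie outside the work area")
  }
  if (length(msg)) msg else TRUE
})

#' Regularized voltage-space mesh of the calibration surfaces
#'
#' Result of biharmonic-spline regridding of the sparse voltage-space
#' anchors: the inverse surfaces f1 (x_cm) and g1 (y_cm) evaluated on a
#' regular lattice over the anchors' voltage bounding box.
#'
#' @slot gridXv,gridYv lattice node coordinates per axis (volts).
#' @slot valuesXcm,valuesYcm surface values, \code{length(gridXv)} x
#'   \code{length(gridYv)} matrices.
#' @slot anchors the anchor data.frame the mesh was built from.
#' @slot resolution nodes per axis.
#' @export
setClass("RegularizedMesh",
  representation(
    gridXv     = "numeric",
    gridYv     = "numeric",
    valuesXcm  = "matrix",
    valuesYcm  = "matrix",
    anchors    = "data.frame",
    resolution = "integer"
  )
)

#' A fitted voltage-to-centimetre calibration model
#'
#' Bivariate polynomial surfaces \code{x_cm = f1(X_V, Y_V)},
#' \code{y_cm = g1(X_V, Y_V)} of total degree 2, 3 or 4, fitted by
#' least squares on voltage coordinates normalized per channel to
#' [-1, 1].  Evaluation outside the fitted voltage box is flagged as
#' extrapolation, never refused, to honour a streaming contract.
#'
#' @slot order total polynomial degree (2, 3 or 4).
#' @slot coeffsX,coeffsY named coefficient vectors on the normalized
#'   scale; names \code{c_ij} denote the monomial \code{u^i v^j}.
#' @slot normalization list with \code{center} and \code{halfwidth}
#'   (2-vectors, volts) of the per-channel affine scaling.
#' @slot validVoltageBox 2x2 matrix, rows = channels, cols = lo/hi, the
#'   voltage domain covered by the fit.
#' @slot fitResiduals per-anchor data.frame of cm residuals.
#' @slot provenance list: fit target (mesh/anchors), regrid resolution,
#'   session metadata.
#' @export
setClass("CalibrationModel",
  representation(
    order           = "integer",
    coeffsX         = "numeric",
    coeffsY         = "numeric",
    normalization   = "list",
    validVoltageBox = "matrix",
    fitResiduals    = "data.frame",
    provenance      = "list"
  )
)

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (!object@order %in% 2:4)
    msg <- c(msg, "order must be 2, 3 or 4")
  nb <- (object@order + 1) * (object@order + 2) / 2
  if (length(object@coeffsX) != nb || length(object@coeffsY) != nb)
    msg <- c(msg, sprintf("expected %d coefficients per surface for order %d",
                          nb, object@order))
  if (!all(c("center", "halfwidth") %in% names(object@normalization)))
    msg <- c(msg, "normalization must carry center and halfwidth")
  if (!identical(dim(object@validVoltageBox), c(2L, 2L)))
    msg <- c(msg, "validVoltageBox must be a 2x2 matrix")
  if (nrow(object@fitResiduals) > 0 &&
      !all(is.finite(object@fitResiduals$res_x_cm)))
    msg <- c(msg, "fit residuals must be finite")
  if (length(msg)) msg else TRUE
})

#' A drift-correction voltage offset
#'
#' The constant voltage shift that realigns a drifted recording with
#' the calibration epoch, estimated from a fixation of the centre
#' target of the calibration grid: \code{dv = mean(calibration-epoch
#' centre voltages) - mean(current centre voltages)}.  Corrected
#' voltages are \code{raw + dv}.
#'
#' @slot dv the offset (volts, 2-vector).
#' @slot estimatedAt timestamp (ms) of the estimation fixation.
#' @slot centerTarget the centre-target position used (cm).
#' @slot nSamples number of samples in the estimation fixation.
#' @export
setClass("DriftOffset",
  representation(
    dv           = "numeric",
    estimatedAt  = "numeric",
    centerTarget = "numeric",
    nSamples     = "integer"
  )
)

setValidity("DriftOffset", function(object) {
  msg <- character()
  if (length(object@dv) != 2L || !all(is.finite(object@dv)))
    msg <- c(msg, "dv must be a finite 2-vector")
  if (object@nSamples <= 0L)
    msg <- c(msg, "nSamples must be positive")
  if (length(msg)) msg else TRUE
})
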