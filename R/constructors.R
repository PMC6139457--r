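#' Construct a rig geometry
#'
#' The defaults describe a plausible primate rig with a horizontal
#' display viewed from above: the work-area centre 30 cm ahead of and
#' 25 cm below the eyeball centre, a 20 x 9 cm work area and a 60 Hz
#' display refreshed top-to-bottom over a 30 cm image.  The eye-to-
#' workspace offsets are a declared fixture of the simulator, not a
#' measured rig constant.
#'
#' @param screenOriginInEyeFrame numeric(3), cm; the screen-frame
#'   origin in the eye-centred frame.  Third component must be
#'   negative (display below the eye).
#' @param workAreaCm numeric(2), cm; work-area width and depth.
#' @param refreshHz display refresh rate, Hz.
#' @param screenExtentCm vertical image extent swept per refresh, cm.
#' @param referenceSpots 2x2 matrix of two reference screen points
#'   (cm); defaults to the work-area centre and far edge midpoint.
#' @param elevationConvention \code{"from-horizontal"} (default) or
#'   \code{"from-vertical"}; see [vectorToPolar()].
#' @return a validated [RigGeometry-class].
#' @examples
#' g <- rigGeometry()
#' screenToEyeFrame(c(0, 0), g)
#' @export
rigGeometry <- function(screenOriginInEyeFrame = c(0, 30, -25),
                        workAreaCm = c(20, 9),
                        refreshHz = 60,
                        screenExtentCm = 30,
                        referenceSpots = NULL,
                        elevationConvention = c("from-horizontal",
                                                "from-vertical")) {
  elevationConvention <- match.arg(elevationConvention)
  if (is.null(referenceSpots))
    referenceSpots <- rbind(c(0, 0), c(0, workAreaCm[2] / 2))
  new("RigGeometry",
      screenOriginInEyeFrame = as.numeric(screenOriginInEyeFrame),
      workAreaCm = as.numeric(workAreaCm),
      refreshHz = as.numeric(refreshHz),
      screenExtentCm = as.numeric(screenExtentCm),
      referenceSpots = referenceSpots,
      elevationConvention = elevationConvention)
}

#' Construct the pinhole artificial-eye forward model
#'
#' Defaults place the tracker camera 40 cm ahead of and 12 cm below
#' the eye (behind the display, looking back at the eyeball), with a
#' 1.25 cm pupil orbit radius and gains chosen so the default 20 x 9 cm
#' work area maps to a few volts per channel, well inside the +/-10 V
#' saturation range.  The gain/offset defaults span, rather than copy,
#' the adjustment range of a hardware tracker interface.
#'
#' @param eyeballRadiusCm pupil orbit radius, cm.
#' @param cameraPositionCm camera pinhole in the eye-centred frame, cm.
#' @param cameraAxis optical axis; default points at the eyeball centre.
#' @param focalGainV volts per unit image coordinate, per channel.
#' @param voltageOffsetV additive offset, volts; default recentres the
#'   vertical channel near zero for the default rig.
#' @param voltageRangeV 2x2 matrix (channels x lo/hi) of saturation
#'   limits, volts.
#' @return a [PinholeForwardModel-class].
#' @export
pinholeForwardModel <- function(eyeballRadiusCm = 1.25,
                                cameraPositionCm = c(0, 40, -12),
                                cameraAxis = NULL,
                                focalGainV = c(400, 400),
                                voltageOffsetV = c(0, 4.8),
                                voltageRangeV = rbind(c(-10, 10), c(-10, 10))) {
  if (is.null(cameraAxis)) {
    cameraAxis <- -cameraPositionCm / sqrt(sum(cameraPositionCm^2))
  }
  new("PinholeForwardModel",
      eyeballRadiusCm = as.numeric(eyeballRadiusCm),
      cameraPositionCm = as.numeric(cameraPositionCm),
      cameraAxis = as.numeric(cameraAxis),
      focalGainV = as.numeric(focalGainV),
      voltageOffsetV = as.numeric(voltageOffsetV),
      voltageRangeV = voltageRangeV)
}

#' Construct an analytically invertible forward model
#'
#' The voltage-to-cm inverse is the bivariate polynomial pair given by
#' \code{coeffsX}/\code{coeffsY}; the forward (cm-to-volts) direction is
#' solved by Newton iteration at evaluation time.  The default is a
#' mildly nonlinear quartic-invertible map over the default work area.
#'
#' @param order total degree of the inverse polynomials.
#' @param coeffsX,coeffsY named coefficient vectors (names
#'   \code{c_ij} = coefficient of \code{XV^i YV^j}); defaults give
#'   \code{x = 4 XV + 0.01 XV^4 + 0.2 YV^2} and
#'   \code{y = 2.5 YV + 0.1 YV^2 + 0.02 YV^4}, a mildly distorted
#'   triangular map that stays strictly monotone over the default work
#'   area.
#' @param voltageOffsetV,voltageRangeV as in [pinholeForwardModel()].
#' @return a [PolynomialInverseModel-class].
#' @export
polynomialInverseModel <- function(order = 4L,
                                   coeffsX = c(c_10 = 4, c_40 = 0.01,
                                               c_02 = 0.2),
                                   coeffsY = c(c_01 = 2.5, c_02 = 0.1,
                                               c_04 = 0.02),
                                   voltageOffsetV = c(0, 0),
                                   voltageRangeV = rbind(c(-10, 10),
                                                         c(-10, 10))) {
  new("PolynomialInverseModel",
      order = as.integer(order),
      coeffsX = coeffsX, coeffsY = coeffsY,
      voltageOffsetV = as.numeric(voltageOffsetV),
      voltageRangeV = voltageRangeV)
}

#' Construct a noise model
#'
#' All defaults are zero (a noise-free artificial eye rigidly mounted
#' in the rig).  Monkey-grade recording noise corresponds to
#' \code{sampleNoiseDegRMS = 0.048} with per-trial fixational scatter
#' \code{trialScatterDegSD = 0.1}.
#'
#' @param sampleNoiseDegRMS RMS of the per-sample angular jitter
#'   magnitude, degrees.
#' @param voltageNoiseV additive sensor noise SD, volts.
#' @param trialScatterDegSD per-trial fixation offset SD per polar
#'   axis, degrees.
#' @param headShiftV constant voltage offset, volts.
#' @param blinkProb per-trial blink probability.
#' @return a [NoiseModel-class].
#' @export
noiseModel <- function(sampleNoiseDegRMS = 0,
                       voltageNoiseV = 0,
                       trialScatterDegSD = 0,
                       headShiftV = c(0, 0),
                       blinkProb = 0) {
  new("NoiseModel",
      sampleNoiseDegRMS = as.numeric(sampleNoiseDegRMS),
      voltageNoiseV = as.numeric(voltageNoiseV),
      trialScatterDegSD = as.numeric(trialScatterDegSD),
      headShiftV = as.numeric(headShiftV),
      blinkProb = as.numeric(blinkProb))
}
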