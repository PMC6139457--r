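#' Map screen positions to raw tracker voltages
#'
#' Evaluates the simulator's forward relationship
#' \code{X_V = f(X_cm, Y_cm)}, \code{Y_V = g(X_cm, Y_cm)} for one or
#' more gaze points on the work area.  Deterministic; noise is added
#' separately by [simulateFixationSession()].
#'
#' @param model a [TrackerForwardModel-class].
#' @param points numeric 2-vector or n x 2 matrix of screen positions
#'   (cm, work-area-centred frame).
#' @param geometry a [RigGeometry-class].
#' @return an n x 2 matrix of voltages with attribute
#'   \code{"saturated"}, a logical vector marking points clipped at the
#'   voltage range.
#' @export
setGeneric("forwardVoltages", function(model, points, geometry)
  standardGeneric("forwardVoltages"))

#' Apply a constant head-shift offset to a session or voltage matrix
#'
#' Adds a constant voltage offset to every sample, emulating the global
#' signal offset a head displacement induces in the tracker image.
#'
#' @param x a [FixationSession-class] or n x 2 voltage matrix.
#' @param dv 2-vector of volts to add.
#' @return an object of the same class as \code{x}; session provenance
#'   accumulates the shift.
#' @export
setGeneric("applyHeadShift", function(x, dv) standardGeneric("applyHeadShift"))

#' Apply a drift-correction offset
#'
#' Adds the estimated offset \code{dv} to the raw voltages so that the
#' corrected signal re-enters the efficient range of the calibration
#' model; timestamps and all other columns are untouched.
#'
#' @param x a [FixationSession-class] or n x 2 voltage matrix.
#' @param drift a [DriftOffset-class] (or plain 2-vector).
#' @return same class as \code{x}.
#' @export
setGeneric("applyDrift", function(x, drift) standardGeneric("applyDrift"))

#' @rdname sessionSamples
#' @export
setGeneric("sessionSamples", function(x) standardGeneric("sessionSamples"))

#' @rdname sessionSamples
#' @export
setGeneric("sessionGeometry", function(x) standardGeneric("sessionGeometry"))

#' @rdname sessionSamples
#' @export
setGeneric("sessionRate", function(x) standardGeneric("sessionRate"))

#' @rdname sessionSamples
#' @export
setGeneric("sessionProvenance", function(x) standardGeneric("sessionProvenance"))

#' @rdname modelAccessors
#' @export
setGeneric("modelOrder", function(x) standardGeneric("modelOrder"))

#' @rdname modelAccessors
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))

#' @rdname modelAccessors
#' @export
setGeneric("validVoltageBox", function(x) standardGeneric("validVoltageBox"))

#' @rdname modelAccessors
#' @export
setGeneric("fitResiduals", function(x) standardGeneric("fitResiduals"))

#' @rdname driftAccessors
#' @export
setGeneric("driftVoltage", function(x) standardGeneric("driftVoltage"))
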