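## Applying a CalibrationModel to raw voltage streams: drift
## correction, polynomial evaluation, and conversion to visual angles.

#' Estimate a drift-correction offset from centre-target fixations
#'
#' The offset is the difference between the mean voltages recorded at
#' the calibration epoch and now, both while fixating the target at the
#' centre of the calibration grid:
#' \code{dv = mean(calibration) - mean(current)}.  Adding \code{dv} to
#' the raw signal restores calibration-epoch coordinates.
#'
#' @param currentVolts n x 2 matrix of voltages from the current
#'   centre fixation.
#' @param calibrationVolts m x 2 matrix from the calibration-epoch
#'   centre fixation.
#' @param centerTarget the centre-target position (cm), recorded for
#'   provenance.
#' @param estimatedAt timestamp (ms) of the estimation fixation.
#' @return a [DriftOffset-class].
#' @export
estimateDrift <- function(currentVolts, calibrationVolts,
                          centerTarget = c(0, 0), estimatedAt = NA_real_) {
  currentVolts <- .as_points(currentVolts, 2L, "currentVolts")
  calibrationVolts <- .as_points(calibrationVolts, 2L, "calibrationVolts")
  if (nrow(currentVolts) == 0L || nrow(calibrationVolts) == 0L)
    stop("empty voltage set: cannot estimate drift")
  new("DriftOffset",
      dv = colMeans(calibrationVolts) - colMeans(currentVolts),
      estimatedAt = as.numeric(estimatedAt),
      centerTarget = as.numeric(centerTarget),
      nSamples = nrow(currentVolts))
}

#' @describeIn applyDrift correct every sample of a session.
#' @export
setMethod("applyDrift",
  signature(x = "FixationSession", drift = "DriftOffset"),
  function(x, drift) {
    x@samples$xv_volts <- x@samples$xv_volts + drift@dv[1]
    x@samples$yv_volts <- x@samples$yv_volts + drift@dv[2]
    x@provenance$drift_corrections <-
      c(x@provenance$drift_corrections, list(drift@dv))
    x
  })

#' @describeIn applyDrift correct a plain n x 2 voltage matrix.
#' @export
setMethod("applyDrift",
  signature(x = "matrix", drift = "DriftOffset"),
  function(x, drift) sweep(x, 2, -drift@dv))

#' @rdname driftAccessors
#' @export
setMethod("driftVoltage", "DriftOffset", function(x) x@dv)

setMethod("show", "DriftOffset", function(object) {
  cat(sprintf("DriftOffset: dv = (%.4g, %.4g) V from %d samples\n",
              object@dv[1], object@dv[2], object@nSamples))
})

#' Convert raw voltages to gaze positions
#'
#' Evaluates the fitted surfaces f1 and g1 at the given voltages after
#' re-applying the stored normalization.  Voltages outside the fitted
#' voltage box are evaluated anyway but flagged as extrapolation;
#' non-finite voltages yield flagged invalid rows rather than an error,
#' honouring a streaming contract.  Cost is O(basis size) per sample,
#' suitable for 1 kHz streams.
#'
#' @param volts 2-vector or n x 2 matrix of raw (drift-corrected)
#'   voltages.
#' @param model a [CalibrationModel-class].
#' @return data.frame with \code{x_cm}, \code{y_cm},
#'   \code{extrapolated}, \code{valid}.
#' @export
voltagesToGaze <- function(volts, model) {
  if (is.null(dim(volts))) volts <- matrix(volts, ncol = 2L)
  volts <- as.matrix(volts)
  if (ncol(volts) != 2L) stop("'volts' must have two channels")
  ok <- is.finite(volts[, 1]) & is.finite(volts[, 2])
  box <- model@validVoltageBox
  extra <- ok & (volts[, 1] < box[1, 1] | volts[, 1] > box[1, 2] |
                 volts[, 2] < box[2, 1] | volts[, 2] > box[2, 2])
  out <- data.frame(x_cm = rep(NA_real_, nrow(volts)),
                    y_cm = NA_real_, extrapolated = extra, valid = ok)
  if (any(ok)) {
    U <- .normalizeVolts(volts[ok, , drop = FALSE], model@normalization)
    out$x_cm[ok] <- .polyEval(model@coeffsX, U[, 1], U[, 2])
    out$y_cm[ok] <- .polyEval(model@coeffsY, U[, 1], U[, 2])
  }
  out
}

#' Reconstruct per-sample gaze for a whole session
#'
#' Applies an optional drift correction, then [voltagesToGaze()] and
#' [gazeToAngles()] to every sample of the session.
#'
#' @param session a [FixationSession-class].
#' @param model a [CalibrationModel-class].
#' @param drift optional [DriftOffset-class].
#' @return data.frame with the session's id/target/time columns plus
#'   \code{x_cm}, \code{y_cm}, \code{theta_deg}, \code{phi_deg},
#'   \code{extrapolated}, \code{valid}.
#' @export
reconstructSession <- function(session, model, drift = NULL) {
  if (!is.null(drift)) session <- applyDrift(session, drift)
  s <- sessionSamples(session)
  gz <- voltagesToGaze(as.matrix(s[, c("xv_volts", "yv_volts")]), model)
  ang <- data.frame(theta_deg = rep(NA_real_, nrow(gz)), phi_deg = NA_real_)
  ok <- gz$valid & is.finite(gz$x_cm)
  if (any(ok)) {
    a <- gazeToAngles(cbind(gz$x_cm[ok], gz$y_cm[ok]),
                      sessionGeometry(session))
    ang$theta_deg[ok] <- a$theta_deg
    ang$phi_deg[ok] <- a$phi_deg
  }
  cbind(s[, c("trial_id", "target_x_cm", "target_y_cm", "t_ms")],
        gz[, c("x_cm", "y_cm")], ang,
        gz[, c("extrapolated", "valid")],
        valid_sample = s$valid & gz$valid)
}

#' Reconstruct one gaze position per trial
#'
#' The per-trial eye position is the mean of the retained samples over
#' the fixation window (after [selectSamples()] cleaning), converted to
#' cm through the model — the per-trial summary used for calibration
#' validation.
#'
#' @param session a [FixationSession-class].
#' @param model a [CalibrationModel-class].
#' @param drift optional [DriftOffset-class].
#' @param voltageRange,outlierSD sample-selection policy.
#' @return data.frame with one row per usable trial: \code{trial_id},
#'   target position, mean-voltage gaze \code{x_cm}, \code{y_cm},
#'   angles, and \code{n_samples}.
#' @export
reconstructTrials <- function(session, model, drift = NULL,
                              voltageRange = NULL, outlierSD = 5) {
  if (!is.null(drift)) session <- applyDrift(session, drift)
  s <- sessionSamples(session)
  g <- sessionGeometry(session)
  rows <- lapply(split(s, s$trial_id), function(tr) {
    sel <- selectSamples(tr, voltageRange, outlierSD)
    if (!sel$report$usable) return(NULL)
    v <- colMeans(as.matrix(sel$samples[, c("xv_volts", "yv_volts")]))
    gz <- voltagesToGaze(v, model)
    data.frame(trial_id = tr$trial_id[1],
               target_x_cm = tr$target_x_cm[1],
               target_y_cm = tr$target_y_cm[1],
               x_cm = gz$x_cm, y_cm = gz$y_cm,
               extrapolated = gz$extrapolated,
               n_samples = sel$report$n_kept)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("no usable trials in session")
  a <- gazeToAngles(cbind(out$x_cm, out$y_cm), g)
  out$theta_deg <- a$theta_deg
  out$phi_deg <- a$phi_deg
  out <- out[order(out$trial_id), ]
  rownames(out) <- NULL
  out
}
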