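## Validation battery: median-distance accuracy, two precision
## measures, rank-sum distribution comparisons, and the
## discriminability-preservation procedure.

#' Per-trial angular errors of reconstructed gaze
#'
#' For each reconstructed trial, the angular distance between the gaze
#' vector and the target vector (degrees of visual angle), plus the
#' signed per-axis errors in theta and phi obtained by aligning each
#' trial on its target.
#'
#' @param trials data.frame from [reconstructTrials()] (needs
#'   \code{x_cm}, \code{y_cm}, \code{target_x_cm}, \code{target_y_cm},
#'   \code{trial_id}).
#' @param geometry a [RigGeometry-class].
#' @return data.frame: \code{trial_id}, \code{angular_error_deg},
#'   \code{dtheta_deg}, \code{dphi_deg}.
#' @export
angularErrors <- function(trials, geometry) {
  u <- screenToEyeFrame(cbind(trials$x_cm, trials$y_cm), geometry)
  v <- screenToEyeFrame(cbind(trials$target_x_cm, trials$target_y_cm),
                        geometry)
  pg <- vectorToPolar(u, geometry@elevationConvention)
  pt <- vectorToPolar(v, geometry@elevationConvention)
  data.frame(trial_id = trials$trial_id,
             angular_error_deg = angularDistance(u, v),
             dtheta_deg = pg$theta_deg - pt$theta_deg,
             dphi_deg = pg$phi_deg - pt$phi_deg)
}

#' Accuracy: median absolute distance to target
#'
#' @param errors numeric vector of per-trial angular errors (degrees),
#'   e.g. \code{angularErrors(...)$angular_error_deg}.
#' @return median absolute angular error, degrees.
#' @export
accuracy <- function(errors) {
  if (!length(errors)) stop("no errors supplied")
  stats::median(abs(errors))
}

#' Precision: interquartile range of the error distribution
#'
#' Quantiles use the linear-interpolation rule (type 7), recorded here
#' as the package's fixed convention.
#'
#' @param errors numeric vector of per-trial angular errors (degrees).
#' @return interquartile range, degrees.
#' @export
precisionIQR <- function(errors) {
  if (!length(errors)) stop("no errors supplied")
  stats::IQR(errors, type = 7)
}

#' Precision: sample-to-sample RMS within a fixation
#'
#' Root mean square of the angular distances between successive
#' samples of a single fixation trial — the conventional tracker-noise
#' figure, insensitive to slow drifts.
#'
#' @param gaze n x 2 matrix of successive on-screen gaze samples (cm)
#'   of one fixation, in time order.
#' @param geometry a [RigGeometry-class].
#' @return RMS sample-to-sample angular distance, degrees.
#' @export
precisionRMS <- function(gaze, geometry) {
  gaze <- .as_points(gaze, 2L, "gaze")
  n <- nrow(gaze)
  if (n < 2L) stop("need at least 2 samples for RMS precision")
  u <- screenToEyeFrame(gaze, geometry)
  a <- angularDistance(u[-n, , drop = FALSE], u[-1, , drop = FALSE])
  sqrt(mean(a^2))
}

#' Compare two error distributions (Wilcoxon rank sum)
#'
#' Two-sided rank-sum test, the distribution comparison used to check
#' that drift-corrected recordings match the pre-movement ones and
#' that random-target errors match grid-target errors.
#'
#' @param a,b numeric vectors of angular errors (degrees).
#' @return two-sided p-value.
#' @export
compareDistributions <- function(a, b) {
  stats::wilcox.test(a, b, exact = FALSE)$p.value
}

#' Bracketing mean shifts around the significance boundary
#'
#' For a normal eye-position distribution of SD \code{sigma} sampled
#' \code{n} times, finds the mean shift at which the expected
#' two-sample t-statistic crosses the \code{alpha} significance
#' boundary, \code{delta* = t_crit * sigma * sqrt(2/n)}, and returns
#' the pair bracketing it at a distance of a tenth of the standard
#' deviation: the maximal shift that stays non-significant
#' (\code{delta* - sigma/20}) and the minimal shift that becomes
#' significant (\code{delta* + sigma/20}).  Defined on the expected
#' t-statistic, so the returned shifts are deterministic.
#'
#' @param sigma SD of the voltage distribution on the shifted axis.
#' @param n samples per distribution.
#' @param alpha significance level.
#' @return named numeric: \code{max_nonsignificant},
#'   \code{min_significant} (same units as \code{sigma}).
#' @export
shiftBoundaries <- function(sigma, n, alpha = 0.05) {
  if (sigma <= 0 || n < 2) stop("need sigma > 0 and n >= 2")
  tcrit <- stats::qt(1 - alpha / 2, df = 2 * n - 2)
  center <- tcrit * sigma * sqrt(2 / n)
  c(max_nonsignificant = center - sigma / 20,
    min_significant = center + sigma / 20)
}

#' Discriminability of eye-position distributions after reconstruction
#'
#' The headline integrity check of the conversion chain: voltage
#' distributions that differ significantly in eye-position space must
#' still differ after transformation to gaze angles, and ones that do
#' not must not.  A normal voltage distribution (given per-channel
#' mean and SD, from a centre-target fixation) is drawn once; for each
#' requested axis the drawn sample is translated by the
#' [shiftBoundaries()] amounts — shifting the distribution itself, so
#' its significance versus the original holds by construction in
#' voltage space.  Original and shifted samples are pushed through the
#' calibration model and converted to polar angles, then compared with
#' Student's t-tests (means) and Fisher's variance-ratio f-tests
#' (shape) on theta and phi; the input-space p-value on the shifted
#' channel is reported alongside for the preservation comparison.
#'
#' @param model a fitted [CalibrationModel-class].
#' @param geometry a [RigGeometry-class].
#' @param eyeMean,eyeSD per-channel mean and SD of the centre-fixation
#'   voltage distribution (volts, 2-vectors).
#' @param n draws per distribution.
#' @param axes which voltage axes to shift.
#' @param alpha significance level for the boundary construction.
#' @param seed RNG seed.
#' @return data.frame with one row per (axis, shift level):
#'   \code{shift_axis}, \code{level} (\code{"min_significant"} or
#'   \code{"max_nonsignificant"}), \code{shift_v}, the voltage-space
#'   p-value \code{t_input} on the shifted channel, and angle-space
#'   p-values \code{t_theta}, \code{t_phi}, \code{f_theta},
#'   \code{f_phi}.
#' @export
discriminabilityTable <- function(model, geometry, eyeMean, eyeSD,
                                  n = 1000L, axes = c("x", "y"),
                                  alpha = 0.05, seed = 1L) {
  if (length(model@coeffsX) == 0L) stop("model is not fitted")
  axes <- match.arg(axes, c("x", "y"), several.ok = TRUE)
  runif(1)
  oldSeed <- .Random.seed
  on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)
  toAngles <- function(V) {
    gz <- voltagesToGaze(V, model)
    gazeToAngles(cbind(gz$x_cm, gz$y_cm), geometry)
  }
  V0 <- cbind(stats::rnorm(n, eyeMean[1], eyeSD[1]),
              stats::rnorm(n, eyeMean[2], eyeSD[2]))
  orig <- toAngles(V0)
  rows <- list()
  for (ax in axes) {
    ch <- if (ax == "x") 1L else 2L
    bounds <- shiftBoundaries(eyeSD[ch], n, alpha)
    for (lvl in names(bounds)) {
      Vs <- V0
      Vs[, ch] <- Vs[, ch] + bounds[[lvl]]        # translate the sample
      ang <- toAngles(Vs)
      rows[[length(rows) + 1L]] <- data.frame(
        shift_axis = toupper(ax), level = lvl, shift_v = bounds[[lvl]],
        t_input = stats::t.test(Vs[, ch], V0[, ch])$p.value,
        t_theta = stats::t.test(ang$theta_deg, orig$theta_deg)$p.value,
        t_phi   = stats::t.test(ang$phi_deg, orig$phi_deg)$p.value,
        f_theta = stats::var.test(ang$theta_deg, orig$theta_deg)$p.value,
        f_phi   = stats::var.test(ang$phi_deg, orig$phi_deg)$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "alpha") <- alpha
  out
}

#' Full metrics report for a validation session
#'
#' Accuracy (median absolute distance to target), IQR precision, and a
#' per-target breakdown for the per-trial reconstruction of a
#' validation session.
#'
#' @param trials data.frame from [reconstructTrials()].
#' @param geometry a [RigGeometry-class].
#' @return list: \code{accuracy_deg}, \code{precision_iqr_deg},
#'   \code{n_trials}, \code{quantile_rule}, \code{per_target}
#'   data.frame, and the per-trial \code{errors}.
#' @export
metricsReport <- function(trials, geometry) {
  err <- angularErrors(trials, geometry)
  byT <- split(err$angular_error_deg,
               paste(trials$target_x_cm, trials$target_y_cm, sep = "/"))
  per <- data.frame(target = names(byT),
                    accuracy_deg = vapply(byT, stats::median, numeric(1)),
                    n = vapply(byT, length, integer(1)), row.names = NULL)
  list(accuracy_deg = accuracy(err$angular_error_deg),
       precision_iqr_deg = precisionIQR(err$angular_error_deg),
       n_trials = nrow(err),
       quantile_rule = "linear interpolation (type 7)",
       per_target = per,
       errors = err)
}
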