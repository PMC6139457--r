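## Building the voltage -> cm inverse mapping: sample selection,
## per-target anchor averaging, biharmonic regridding of the sparse
## voltage-space points, and bivariate polynomial fitting.

#' Clean the samples of one fixation trial
#'
#' Drops samples flagged invalid, samples outside the valid voltage
#' range, and samples whose channel-wise deviation from the trial
#' median exceeds \code{outlierSD} robust SDs (median absolute
#' deviation scaled to the normal) — a conservative stand-in for
#' blink/saccade removal.
#'
#' @param trial data.frame of one trial's samples (session columns).
#' @param voltageRange optional 2x2 matrix (channels x lo/hi) of
#'   admissible volts; samples outside are rejected.
#' @param outlierSD robust-SD multiple for the outlier rule.
#' @return list with \code{samples} (retained rows) and \code{report}
#'   (counts by rejection reason, and \code{usable}).  A trial whose
#'   samples are all rejected is returned with \code{usable = FALSE},
#'   never silently dropped.
#' @export
selectSamples <- function(trial, voltageRange = NULL, outlierSD = 5) {
  if (nrow(trial) == 0L) stop("empty trial: no samples to select")
  keep <- trial$valid
  nInvalid <- sum(!keep)
  nRange <- 0L
  if (!is.null(voltageRange)) {
    inRange <- trial$xv_volts >= voltageRange[1, 1] &
               trial$xv_volts <= voltageRange[1, 2] &
               trial$yv_volts >= voltageRange[2, 1] &
               trial$yv_volts <= voltageRange[2, 2]
    nRange <- sum(keep & !inRange)
    keep <- keep & inRange
  }
  nOut <- 0L
  if (any(keep)) {
    for (ch in c("xv_volts", "yv_volts")) {
      v <- trial[[ch]][keep]
      med <- stats::median(v)
      s <- stats::mad(v)
      if (s > 0) {
        ok <- abs(trial[[ch]] - med) <= outlierSD * s
        nOut <- nOut + sum(keep & !ok)
        keep <- keep & ok
      }
    }
  }
  list(samples = trial[keep, , drop = FALSE],
       report = list(n_total = nrow(trial), n_kept = sum(keep),
                     n_invalid_flag = nInvalid, n_out_of_range = nRange,
                     n_outlier = nOut, usable = any(keep)))
}

#' Average a session into per-target voltage anchors
#'
#' For each distinct target, averages the retained samples of all its
#' repeats into one mean-voltage anchor — the reference points of the
#' inverse functions f1 and g1.
#'
#' @param session a [FixationSession-class].
#' @param voltageRange,outlierSD passed to [selectSamples()].
#' @return data.frame with one row per target: \code{target_x_cm},
#'   \code{target_y_cm}, \code{xv_volts}, \code{yv_volts} (means),
#'   \code{sd_xv}, \code{sd_yv}, \code{n_samples}, \code{n_trials}.
#' @export
averageAnchors <- function(session, voltageRange = NULL, outlierSD = 5) {
  s <- sessionSamples(session)
  trials <- split(s, s$trial_id)
  kept <- lapply(trials, function(tr) {
    sel <- selectSamples(tr, voltageRange, outlierSD)
    if (sel$report$usable) sel$samples else tr[0, , drop = FALSE]
  })
  kept <- do.call(rbind, kept)
  key <- paste(s$target_x_cm, s$target_y_cm, sep = "/")
  allTargets <- unique(s[, c("target_x_cm", "target_y_cm")])
  allKey <- paste(allTargets$target_x_cm, allTargets$target_y_cm, sep = "/")
  keptKey <- paste(kept$target_x_cm, kept$target_y_cm, sep = "/")
  missing <- setdiff(allKey, keptKey)
  if (length(missing))
    stop("no usable trial for target(s): ", paste(missing, collapse = "; "))
  agg <- lapply(split(kept, keptKey), function(d) {
    data.frame(target_x_cm = d$target_x_cm[1], target_y_cm = d$target_y_cm[1],
               xv_volts = mean(d$xv_volts), yv_volts = mean(d$yv_volts),
               sd_xv = stats::sd(d$xv_volts), sd_yv = stats::sd(d$yv_volts),
               n_samples = nrow(d), n_trials = length(unique(d$trial_id)))
  })
  anchors <- do.call(rbind, agg)
  ## deterministic row order: depth- then width-sorted like the grid
  anchors <- anchors[order(anchors$target_y_cm, anchors$target_x_cm), ]
  rownames(anchors) <- NULL
  anchors
}

## ---- biharmonic (Green's-function) scattered-data interpolation --------

## g(r) = r^2 (ln r - 1), the 2D biharmonic Green's function; g(0) = 0.
.biharmonicG <- function(r) ifelse(r > 0, r^2 * (log(r) - 1), 0)

.biharmonicSolve <- function(xy, f) {
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  if (any(D[upper.tri(D)] < 1e-12)) {
    dup <- which(D < 1e-12 & upper.tri(D), arr.ind = TRUE)
    stop("duplicate anchors at rows ",
         paste(apply(dup, 1, paste, collapse = "&"), collapse = ", "),
         ": interpolation system is singular")
  }
  G <- .biharmonicG(D)
  P <- cbind(1, xy)                       # affine term
  A <- rbind(cbind(G, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(A, c(f, numeric(3)))
  list(w = sol[1:n], a = sol[n + 1:3], xy = xy)
}

.biharmonicEval <- function(fit, xy) {
  D <- sqrt(outer(xy[, 1], fit$xy[, 1], "-")^2 +
            outer(xy[, 2], fit$xy[, 2], "-")^2)
  as.vector(.biharmonicG(D) %*% fit$w + fit$a[1] + xy %*% fit$a[2:3])
}

#' Regrid sparse voltage-space anchors onto a regular lattice
#'
#' The calibration anchors are regular in screen centimetres but
#' sparse and deformed in voltage space.  This interpolates the two
#' inverse surfaces f1 (x_cm) and g1 (y_cm) with the 2D biharmonic
#' Green's function \code{g(r) = r^2 (ln r - 1)} plus an affine term
#' (weights solved exactly through every anchor), then evaluates them
#' on a regular lattice over the anchors' voltage bounding box.  Affine
#' anchor sets are reproduced exactly by construction.
#'
#' @param anchors data.frame from [averageAnchors()] (needs columns
#'   \code{xv_volts}, \code{yv_volts}, \code{target_x_cm},
#'   \code{target_y_cm}), at least 6 non-collinear points.
#' @param resolution lattice nodes per axis.
#' @return a [RegularizedMesh-class].
#' @export
regridBiharmonic <- function(anchors, resolution = 50L) {
  if (nrow(anchors) < 6L)
    stop("need at least 6 anchors for a stable surface")
  xy <- as.matrix(anchors[, c("xv_volts", "yv_volts")])
  if (qr(cbind(1, xy))$rank < 3L)
    stop("anchors are collinear in voltage space")
  fx <- .biharmonicSolve(xy, anchors$target_x_cm)
  fy <- .biharmonicSolve(xy, anchors$target_y_cm)
  gx <- seq(min(xy[, 1]), max(xy[, 1]), length.out = resolution)
  gy <- seq(min(xy[, 2]), max(xy[, 2]), length.out = resolution)
  lat <- as.matrix(expand.grid(gx, gy))
  new("RegularizedMesh",
      gridXv = gx, gridYv = gy,
      valuesXcm = matrix(.biharmonicEval(fx, lat), resolution, resolution),
      valuesYcm = matrix(.biharmonicEval(fy, lat), resolution, resolution),
      anchors = anchors, resolution = as.integer(resolution))
}

#' Evaluate a regularized mesh's surfaces at arbitrary voltages
#'
#' Re-evaluates the biharmonic interpolant (not a lookup) at the given
#' voltage coordinates; used by tests and diagnostics.
#'
#' @param mesh a [RegularizedMesh-class].
#' @param volts n x 2 matrix of voltages.
#' @return n x 2 matrix of (x_cm, y_cm).
#' @export
meshPredict <- function(mesh, volts) {
  volts <- .as_points(volts, 2L, "volts")
  a <- mesh@anchors
  xy <- as.matrix(a[, c("xv_volts", "yv_volts")])
  fx <- .biharmonicSolve(xy, a$target_x_cm)
  fy <- .biharmonicSolve(xy, a$target_y_cm)
  cbind(.biharmonicEval(fx, volts), .biharmonicEval(fy, volts))
}

## ---- polynomial fitting ------------------------------------------------

.normalizeVolts <- function(V, normalization) {
  sweep(sweep(V, 2, normalization$center), 2, normalization$halfwidth, "/")
}

#' Fit bivariate polynomial calibration surfaces
#'
#' Least-squares fit of the inverse surfaces
#' \code{x_cm = f1(X_V, Y_V)}, \code{y_cm = g1(X_V, Y_V)} with the full
#' total-degree basis (6, 10 or 15 terms for orders 2, 3, 4) on
#' voltages normalized per channel to [-1, 1] (the scaling is stored in
#' the model and re-applied at evaluation).  Deterministic.
#'
#' @param data a [RegularizedMesh-class] (fit on the regridded lattice)
#'   or an anchor data.frame (fit directly on the anchors).
#' @param order total polynomial degree, 2 to 4.
#' @return a [CalibrationModel-class].
#' @export
fitPolynomial <- function(data, order = 4L) {
  order <- as.integer(order)
  if (!order %in% 2:4) stop("order must be 2, 3 or 4")
  if (is(data, "RegularizedMesh")) {
    lat <- as.matrix(expand.grid(data@gridXv, data@gridYv))
    V <- lat
    zx <- as.vector(data@valuesXcm)
    zy <- as.vector(data@valuesYcm)
    anchors <- data@anchors
    fitOn <- "mesh"
  } else {
    anchors <- as.data.frame(data)
    V <- as.matrix(anchors[, c("xv_volts", "yv_volts")])
    zx <- anchors$target_x_cm
    zy <- anchors$target_y_cm
    fitOn <- "anchors"
  }
  nb <- (order + 1) * (order + 2) / 2
  if (nrow(V) < nb)
    stop(sprintf("need at least %d points for an order-%d fit", nb, order))
  normalization <- list(
    center = colMeans(apply(V, 2, range)),
    halfwidth = apply(V, 2, function(z) diff(range(z)) / 2))
  if (any(normalization$halfwidth <= 0))
    stop("degenerate voltage extent: cannot normalize")
  U <- .normalizeVolts(V, normalization)
  X <- .polyBasis(U[, 1], U[, 2], order)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop(sprintf(
      "rank-deficient design (rank %d of %d): condition number %.3g",
      qrX$rank, ncol(X), kappa(X)))
  cx <- qr.coef(qrX, zx); cy <- qr.coef(qrX, zy)
  ## residuals reported at the anchors, whichever surface was fitted
  AV <- as.matrix(anchors[, c("xv_volts", "yv_volts")])
  AU <- .normalizeVolts(AV, normalization)
  AX <- .polyBasis(AU[, 1], AU[, 2], order)
  res <- data.frame(target_x_cm = anchors$target_x_cm,
                    target_y_cm = anchors$target_y_cm,
                    res_x_cm = as.vector(AX %*% cx) - anchors$target_x_cm,
                    res_y_cm = as.vector(AX %*% cy) - anchors$target_y_cm)
  new("CalibrationModel",
      order = order,
      coeffsX = stats::setNames(as.vector(cx), colnames(X)),
      coeffsY = stats::setNames(as.vector(cy), colnames(X)),
      normalization = normalization,
      validVoltageBox = unname(t(apply(AV, 2, range))),
      fitResiduals = res,
      provenance = list(fit_on = fitOn, n_points = nrow(V),
                        n_anchors = nrow(anchors)))
}

#' One-call calibration from a fixation session
#'
#' Runs the full calibration chain: trial cleaning, anchor averaging,
#' optional biharmonic regridding, and the polynomial fit.
#'
#' @param session a [FixationSession-class] recorded on the calibration
#'   grid.
#' @param order polynomial order (2-4); the quartic is the default.
#' @param fitOn \code{"mesh"} (regrid first; the default) or
#'   \code{"anchors"} (fit the anchors directly).
#' @param resolution regrid lattice nodes per axis.
#' @param voltageRange,outlierSD sample-selection policy.
#' @return a [CalibrationModel-class].
#' @examples
#' g <- rigGeometry(); fm <- pinholeForwardModel()
#' ses <- simulateFixationSession(calibrationGrid(g), fm, noiseModel(),
#'                                g, seed = 1)
#' m <- calibrate(ses, order = 4)
#' @export
calibrate <- function(session, order = 4L, fitOn = c("mesh", "anchors"),
                      resolution = 50L, voltageRange = NULL, outlierSD = 5) {
  fitOn <- match.arg(fitOn)
  anchors <- averageAnchors(session, voltageRange, outlierSD)
  m <- if (fitOn == "mesh")
    fitPolynomial(regridBiharmonic(anchors, resolution), order)
  else
    fitPolynomial(anchors, order)
  m@provenance$regrid_resolution <-
    if (fitOn == "mesh") as.integer(resolution) else NA_integer_
  m@provenance$session <- sessionProvenance(session)
  m@provenance$geometry <- .geometryToList(sessionGeometry(session))
  ## centre-grid anchor voltages, the reference for later drift estimation
  ctr <- which.min(anchors$target_x_cm^2 + anchors$target_y_cm^2)
  m@provenance$center_target <- c(anchors$target_x_cm[ctr],
                                  anchors$target_y_cm[ctr])
  m@provenance$center_voltages <- c(anchors$xv_volts[ctr],
                                    anchors$yv_volts[ctr])
  m
}

#' Compare calibration models of different orders on validation data
#'
#' Reconstructs per-trial gaze for each model on a shared validation
#' session, computes the angular distance to target, and reports
#' per-model accuracy plus paired t-tests between every model pair.
#'
#' @param models named list of [CalibrationModel-class] objects.
#' @param session validation [FixationSession-class].
#' @param ... passed to [reconstructTrials()].
#' @return list with \code{per_model} (data.frame: mean/median error,
#'   IQR, n) and \code{pairwise} (data.frame of paired t-test
#'   p-values).
#' @export
compareOrders <- function(models, session, ...) {
  if (length(models) < 2L) stop("need at least two models to compare")
  if (is.null(names(models)))
    names(models) <- paste0("order", vapply(models, modelOrder, integer(1)))
  errs <- lapply(models, function(m) {
    tr <- reconstructTrials(session, m, ...)
    angularErrors(tr, sessionGeometry(session))$angular_error_deg
  })
  ns <- vapply(errs, length, integer(1))
  if (length(unique(ns)) != 1L)
    stop("models were evaluated on mismatched trial sets")
  per <- data.frame(
    model = names(models),
    mean_error_deg = vapply(errs, mean, numeric(1)),
    median_error_deg = vapply(errs, stats::median, numeric(1)),
    iqr_deg = vapply(errs, stats::IQR, numeric(1)),
    n_trials = ns, row.names = NULL)
  pairs <- utils::combn(names(models), 2)
  pw <- apply(pairs, 2, function(pr) {
    p <- if (isTRUE(all.equal(errs[[pr[1]]], errs[[pr[2]]]))) 1
         else stats::t.test(errs[[pr[1]]], errs[[pr[2]]],
                            paired = TRUE)$p.value
    data.frame(model_a = pr[1], model_b = pr[2], p_value = p)
  })
  list(per_model = per, pairwise = do.call(rbind, pw))
}

## ---- accessors & show --------------------------------------------------

#' Accessors for CalibrationModel objects
#'
#' @param x a [CalibrationModel-class].
#' @return \code{modelOrder}: the polynomial order;
#'   \code{modelCoefficients}: list with \code{x} and \code{y} named
#'   coefficient vectors; \code{validVoltageBox}: the 2x2 fitted
#'   voltage domain; \code{fitResiduals}: per-anchor cm residuals.
#' @name modelAccessors
#' @export
setMethod("modelOrder", "CalibrationModel", function(x) x@order)

#' @rdname modelAccessors
#' @export
setMethod("modelCoefficients", "CalibrationModel",
          function(x) list(x = x@coeffsX, y = x@coeffsY))

#' @rdname modelAccessors
#' @export
setMethod("validVoltageBox", "CalibrationModel", function(x) x@validVoltageBox)

#' @rdname modelAccessors
#' @export
setMethod("fitResiduals", "CalibrationModel", function(x) x@fitResiduals)

setMethod("show", "CalibrationModel", function(object) {
  r <- object@fitResiduals
  cat(sprintf("CalibrationModel: order-%d bivariate polynomial (%d terms/surface)\n",
              object@order, length(object@coeffsX)))
  cat(sprintf("  fitted on %s (%d points, %d anchors)\n",
              object@provenance$fit_on, object@provenance$n_points,
              object@provenance$n_anchors))
  if (nrow(r) > 0)
    cat(sprintf("  anchor residual RMS: %.4g cm (x), %.4g cm (y)\n",
                sqrt(mean(r$res_x_cm^2)), sqrt(mean(r$res_y_cm^2))))
})

setMethod("show", "RegularizedMesh", function(object) {
  cat(sprintf("RegularizedMesh: %d x %d lattice over [%.3g, %.3g] x [%.3g, %.3g] V\n",
              object@resolution, object@resolution,
              min(object@gridXv), max(object@gridXv),
              min(object@gridYv), max(object@gridYv)))
  cat(sprintf("  built from %d anchors\n", nrow(object@anchors)))
})
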