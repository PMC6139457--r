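## Coordinate frames and angular mathematics shared by all modules.
## Screen frame: planar cm, origin at work-area centre.  Eye frame:
## X' right, Y' ahead, Z' up, origin at the eyeball centre.  All
## user-facing angles are degrees; radians never leave a function.

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

.as_points <- function(p, ncol = 2L, what = "points") {
  if (is.null(dim(p))) {
    if (length(p) != ncol)
      stop(sprintf("'%s' must have %d coordinates", what, ncol))
    p <- matrix(p, nrow = 1L)
  }
  p <- as.matrix(p)
  if (ncol(p) != ncol)
    stop(sprintf("'%s' must have %d columns", what, ncol))
  if (!all(is.finite(p)))
    stop(sprintf("non-finite coordinates in '%s'", what))
  storage.mode(p) <- "double"
  unname(p)
}

#' Express planar gaze positions in the eye-centred frame
#'
#' Translates screen-frame positions (cm on the display plane) into the
#' eye-centred 3D frame by adding the screen-origin offset; because the
#' eye sits at the origin, the result is simultaneously the gaze
#' vector from the eye to that point.
#'
#' @param p screen point(s): 2-vector or n x 2 matrix, cm.
#' @param geometry a [RigGeometry-class].
#' @return n x 3 matrix of eye-frame coordinates (cm), columns X', Y', Z'.
#' @examples
#' g <- rigGeometry(screenOriginInEyeFrame = c(0, 30, -25))
#' screenToEyeFrame(c(10, -5), g)   # -> (10, 25, -25)
#' @export
screenToEyeFrame <- function(p, geometry) {
  p <- .as_points(p, 2L, "p")
  o <- geometry@screenOriginInEyeFrame
  cbind(p[, 1] + o[1], p[, 2] + o[2], rep(o[3], nrow(p)))
}

#' Inverse of [screenToEyeFrame()]
#'
#' Drops eye-frame points back onto the display plane.  Points must lie
#' on that plane (Z' equal to the screen-origin height) to within
#' \code{tol}; gaze \emph{vectors} of arbitrary length are first
#' rescaled onto the plane.
#'
#' @param u n x 3 matrix of eye-frame coordinates or gaze vectors.
#' @param geometry a [RigGeometry-class].
#' @param project if \code{TRUE}, treat rows as gaze directions and
#'   intersect them with the display plane; otherwise require rows to
#'   lie on the plane.
#' @param tol plane tolerance, cm.
#' @return n x 2 matrix of screen coordinates (cm).
#' @export
eyeFrameToScreen <- function(u, geometry, project = FALSE, tol = 1e-6) {
  u <- .as_points(u, 3L, "u")
  o <- geometry@screenOriginInEyeFrame
  if (project) {
    if (any(u[, 3] * o[3] <= 0))
      stop("gaze direction does not intersect the display plane")
    u <- u * (o[3] / u[, 3])
  } else if (any(abs(u[, 3] - o[3]) > tol)) {
    stop("points do not lie on the display plane")
  }
  cbind(u[, 1] - o[1], u[, 2] - o[2])
}

#' Visual-angle distance between gaze vectors
#'
#' The angle subtended at the eye between two gaze directions, defined
#' through the scalar product of the eye-frame vectors,
#' \code{cos(alpha) = u . v / (|u| |v|)}.  Evaluation uses the
#' equivalent \code{atan2(|u x v|, u . v)} form, which is exact for
#' parallel vectors and immune to the precision loss of an arccosine
#' near \code{cos(alpha) = +/-1} (the cosine route would additionally
#' need clamping into [-1, 1] to absorb floating-point overshoot).
#'
#' @param u,v gaze vectors: 3-vectors or n x 3 matrices (recycled
#'   row-wise if one is a single vector), cm.
#' @return angular distance(s) in degrees, in [0, 180].
#' @examples
#' angularDistance(c(1, 0, 0), c(0, 1, 0))   # 90
#' @export
angularDistance <- function(u, v) {
  u <- .as_points(u, 3L, "u"); v <- .as_points(v, 3L, "v")
  if (nrow(u) == 1L && nrow(v) > 1L) u <- u[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(u) > 1L) v <- v[rep(1L, nrow(u)), , drop = FALSE]
  if (nrow(u) != nrow(v)) stop("'u' and 'v' must have matching rows")
  if (any(rowSums(u^2) == 0) || any(rowSums(v^2) == 0))
    stop("degenerate gaze: zero-norm vector")
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  .deg(atan2(sqrt(cx^2 + cy^2 + cz^2), rowSums(u * v)))
}

#' Gaze vectors in polar visual-angle coordinates
#'
#' Transforms eye-frame gaze vectors into \code{(rho, theta, phi)}:
#' \code{rho} is the vector norm (cm); \code{theta} the azimuth of the
#' projection onto the horizontal X'Y' plane, measured from Y' (ahead),
#' positive rightward; \code{phi} the elevation.  Under the default
#' \code{"from-horizontal"} convention phi is measured from the X'Y'
#' plane (negative = below the horizon, as for a display viewed from
#' above); under \code{"from-vertical"} it is the angle from +Z'.
#'
#' @param u gaze vector(s): 3-vector or n x 3 matrix, cm.
#' @param convention elevation convention; see Details.
#' @return data.frame with columns \code{rho_cm}, \code{theta_deg},
#'   \code{phi_deg}.
#' @examples
#' vectorToPolar(c(0, 1, 0))   # straight ahead: theta = phi = 0
#' @export
vectorToPolar <- function(u, convention = c("from-horizontal",
                                            "from-vertical")) {
  convention <- match.arg(convention)
  u <- .as_points(u, 3L, "u")
  rho <- sqrt(rowSums(u^2))
  if (any(rho == 0)) stop("degenerate gaze: zero-norm vector")
  theta <- .deg(atan2(u[, 1], u[, 2]))
  horiz <- sqrt(u[, 1]^2 + u[, 2]^2)
  phi <- if (convention == "from-horizontal")
    .deg(atan2(u[, 3], horiz)) else .deg(atan2(horiz, u[, 3]))
  data.frame(rho_cm = rho, theta_deg = theta, phi_deg = phi)
}

#' Inverse of [vectorToPolar()] (from-horizontal convention)
#'
#' @param rho_cm,theta_deg,phi_deg polar coordinates as returned by
#'   [vectorToPolar()] under the default convention.
#' @return n x 3 matrix of eye-frame coordinates.
#' @export
polarToVector <- function(rho_cm, theta_deg, phi_deg) {
  th <- .rad(theta_deg); ph <- .rad(phi_deg)
  cbind(rho_cm * cos(ph) * sin(th),
        rho_cm * cos(ph) * cos(th),
        rho_cm * sin(ph))
}

#' Planar gaze to polar visual angles
#'
#' Composition of [screenToEyeFrame()] and [vectorToPolar()]: the
#' standard route from reconstructed on-screen gaze (cm) to visual
#' angles.
#'
#' @param p screen point(s), cm.
#' @param geometry a [RigGeometry-class]; its
#'   \code{elevationConvention} selects the phi convention.
#' @return data.frame \code{rho_cm}, \code{theta_deg}, \code{phi_deg}.
#' @export
gazeToAngles <- function(p, geometry) {
  vectorToPolar(screenToEyeFrame(p, geometry),
                convention = geometry@elevationConvention)
}

#' Display latency of a screen location
#'
#' Raster displays paint the image top to bottom, so a stimulus lights
#' up later the further it sits from the refresh origin.  The model is
#' the linear space--time function \code{latency = slope * distance}
#' with default slope \code{frame_period / screen_extent}; a measured
#' two-point slope (reference and probe photoresistor readings) may
#' override the default.
#'
#' @param distanceCm vertical distance(s) from the reference location,
#'   following the refresh direction; cm, non-negative, within the
#'   screen extent.
#' @param geometry a [RigGeometry-class].
#' @param slopeMsPerCm optional measured slope override, ms/cm.
#' @return latency in ms.
#' @examples
#' g <- rigGeometry(refreshHz = 60, screenExtentCm = 30)
#' displayLatency(30, g)    # one full frame period, 16.7 ms
#' @export
displayLatency <- function(distanceCm, geometry, slopeMsPerCm = NULL) {
  if (any(!is.finite(distanceCm)) || any(distanceCm < 0))
    stop("distanceCm must be non-negative")
  if (any(distanceCm > geometry@screenExtentCm + 1e-9))
    stop("distanceCm exceeds the screen extent")
  if (is.null(slopeMsPerCm))
    slopeMsPerCm <- (1000 / geometry@refreshHz) / geometry@screenExtentCm
  slopeMsPerCm * distanceCm
}
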