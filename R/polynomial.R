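## Bivariate polynomial machinery shared by the simulator's invertible
## forward model and the calibration fits.  Basis: full total-degree
## basis { u^i v^j : i + j <= order }, coefficient names "c_ij".

.polyTermNames <- function(order) {
  idx <- .polyExponents(order)
  sprintf("c_%d%d", idx[, 1], idx[, 2])
}

.polyExponents <- function(order) {
  out <- NULL
  for (i in 0:order)
    for (j in 0:(order - i))
      out <- rbind(out, c(i, j))
  out
}

.polyBasis <- function(u, v, order) {
  idx <- .polyExponents(order)
  X <- matrix(NA_real_, length(u), nrow(idx))
  for (k in seq_len(nrow(idx)))
    X[, k] <- u^idx[k, 1] * v^idx[k, 2]
  colnames(X) <- sprintf("c_%d%d", idx[, 1], idx[, 2])
  X
}

## Evaluate a named coefficient vector (possibly sparse) at (u, v).
.polyEval <- function(coeffs, u, v) {
  idx <- .parseCoefNames(names(coeffs))
  val <- numeric(length(u))
  for (k in seq_along(coeffs))
    val <- val + coeffs[k] * u^idx[k, 1] * v^idx[k, 2]
  val
}

## Partial derivatives wrt u and v, as an n x 2 gradient per point.
.polyGrad <- function(coeffs, u, v) {
  idx <- .parseCoefNames(names(coeffs))
  du <- numeric(length(u)); dv <- numeric(length(u))
  for (k in seq_along(coeffs)) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (i > 0) du <- du + coeffs[k] * i * u^(i - 1) * v^j
    if (j > 0) dv <- dv + coeffs[k] * u^i * j * v^(j - 1)
  }
  cbind(du, dv)
}

.parseCoefNames <- function(nms) {
  if (is.null(nms) || !all(grepl("^c_[0-9][0-9]$", nms)))
    stop("coefficient names must follow the 'c_ij' convention")
  cbind(as.integer(substr(nms, 3, 3)), as.integer(substr(nms, 4, 4)))
}
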