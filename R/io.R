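## Plain-text formats: session CSV with a commented metadata header,
## calibration-model JSON, and YAML run configuration.  All writes are
## atomic (temp file in the target directory, then rename).

.atomicWrite <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file into place at ", path)
  invisible(path)
}

.geometryToList <- function(g) {
  list(screen_origin_in_eye_frame = g@screenOriginInEyeFrame,
       work_area_cm = g@workAreaCm,
       refresh_hz = g@refreshHz,
       screen_extent_cm = g@screenExtentCm,
       elevation_convention = g@elevationConvention)
}

.geometryFromList <- function(l) {
  rigGeometry(screenOriginInEyeFrame = as.numeric(l$screen_origin_in_eye_frame),
              workAreaCm = as.numeric(l$work_area_cm),
              refreshHz = as.numeric(l$refresh_hz),
              screenExtentCm = as.numeric(l$screen_extent_cm),
              elevationConvention = l$elevation_convention)
}

#' Write a fixation session to CSV
#'
#' The format is a plain CSV of per-sample records preceded by
#' \code{#}-commented header lines carrying the units declaration,
#' sampling rate and rig geometry.  Provenance goes to a JSON sidecar
#' (\code{<path>.provenance.json}).  Coordinates are screen-frame cm
#' with the origin at the work-area centre, y increasing away from the
#' body; this is asserted at read time.
#'
#' @param session a [FixationSession-class].
#' @param path output file path.
#' @param sidecar write the provenance sidecar? (default TRUE)
#' @return the path, invisibly.
#' @export
writeSession <- function(session, path, sidecar = TRUE) {
  g <- sessionGeometry(session)
  hdr <- c(
    "# gazecal session v1",
    "# units: positions=cm voltages=volts time=ms",
    sprintf("# rate_hz: %g", sessionRate(session)),
    sprintf("# screen_origin_in_eye_frame: %s",
            paste(g@screenOriginInEyeFrame, collapse = " ")),
    sprintf("# work_area_cm: %s", paste(g@workAreaCm, collapse = " ")),
    sprintf("# refresh_hz: %g", g@refreshHz),
    sprintf("# screen_extent_cm: %g", g@screenExtentCm),
    sprintf("# elevation_convention: %s", g@elevationConvention))
  .atomicWrite(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(sessionSamples(session), con, row.names = FALSE)
  })
  if (sidecar)
    .atomicWrite(paste0(path, ".provenance.json"), function(tmp)
      jsonlite::write_json(sessionProvenance(session), tmp,
                           auto_unbox = TRUE, digits = NA, null = "null"))
  invisible(path)
}

.parseHeader <- function(lines) {
  kv <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^#\\s*([a-z_]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  kv
}

#' Read a fixation session from CSV
#'
#' Inverse of [writeSession()]; validates the units declaration, the
#' required columns, per-row parseability (malformed rows are reported
#' with their line numbers) and strictly increasing timestamps within
#' each trial.
#'
#' @param path file written by [writeSession()].
#' @return a [FixationSession-class] (provenance restored from the
#'   sidecar when present).
#' @export
readSession <- function(path) {
  lines <- readLines(path)
  isHdr <- grepl("^#", lines)
  nHdr <- match(FALSE, isHdr) - 1L
  kv <- .parseHeader(lines[seq_len(nHdr)])
  if (is.null(kv$units) ||
      !identical(kv$units, "positions=cm voltages=volts time=ms"))
    stop("unit declaration missing or mismatched in ", path)
  rate <- as.numeric(kv$rate_hz)
  if (!is.finite(rate) || rate <= 0)
    stop("invalid sampling rate in header of ", path)
  body <- lines[!isHdr]
  d <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  missingCols <- setdiff(.session_cols, names(d))
  if (length(missingCols))
    stop("missing column(s) in ", path, ": ",
         paste(missingCols, collapse = ", "))
  num <- c("target_x_cm", "target_y_cm", "t_ms", "xv_volts", "yv_volts")
  bad <- !vapply(seq_len(nrow(d)), function(i)
    all(suppressWarnings(is.finite(as.numeric(d[i, num])))), logical(1))
  if (any(bad))
    stop("malformed data row(s) at line(s): ",
         paste(nHdr + 1L + which(bad), collapse = ", "))
  d$valid <- as.logical(d$valid)
  geometry <- .geometryFromList(list(
    screen_origin_in_eye_frame = scan(text = kv$screen_origin_in_eye_frame,
                                      quiet = TRUE),
    work_area_cm = scan(text = kv$work_area_cm, quiet = TRUE),
    refresh_hz = as.numeric(kv$refresh_hz),
    screen_extent_cm = as.numeric(kv$screen_extent_cm),
    elevation_convention = kv$elevation_convention))
  prov <- list()
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar))
    prov <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  new("FixationSession", samples = d, geometry = geometry,
      rateHz = rate, provenance = as.list(prov))
}

#' Serialize a calibration model to JSON
#'
#' Layout: \code{order}, \code{basis} (\code{"total_degree"}),
#' \code{coeffs_x}/\code{coeffs_y} keyed \code{c_ij} (coefficient of
#' the normalized monomial \code{u^i v^j}), \code{normalization},
#' \code{valid_voltage_box} and \code{provenance}.
#'
#' @param model a [CalibrationModel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCalibrationModel <- function(model, path) {
  obj <- list(
    order = model@order,
    basis = "total_degree",
    coeffs_x = as.list(model@coeffsX),
    coeffs_y = as.list(model@coeffsY),
    normalization = model@normalization,
    valid_voltage_box = list(
      xv = model@validVoltageBox[1, ], yv = model@validVoltageBox[2, ]),
    provenance = model@provenance)
  ## I(17) significant digits: doubles survive the round trip bit-exactly
  .atomicWrite(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = I(17),
                         null = "null"))
}

#' Read a calibration model from JSON
#'
#' @param path file written by [writeCalibrationModel()].
#' @return a [CalibrationModel-class].
#' @export
readCalibrationModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$basis, "total_degree"))
    stop("unsupported basis in ", path)
  new("CalibrationModel",
      order = as.integer(obj$order),
      coeffsX = unlist(obj$coeffs_x),
      coeffsY = unlist(obj$coeffs_y),
      normalization = list(center = as.numeric(obj$normalization$center),
                           halfwidth = as.numeric(obj$normalization$halfwidth)),
      validVoltageBox = rbind(as.numeric(obj$valid_voltage_box$xv),
                              as.numeric(obj$valid_voltage_box$yv)),
      fitResiduals = data.frame(),
      provenance = as.list(obj$provenance))
}

## ---- run configuration -------------------------------------------------

.cfg_schema <- list(
  geometry = c("screen_origin_in_eye_frame", "work_area_cm", "refresh_hz",
               "screen_extent_cm", "elevation_convention"),
  simulator = c("forward_model", "targets", "n_rows", "n_cols", "n_targets",
                "n_repeats", "window_ms", "rate_hz", "seed", "noise"),
  calibration = c("order", "fit_on", "regrid_resolution", "outlier_sd"),
  paths = c("session", "model", "gaze", "report")
)
.cfg_noise_keys <- c("sample_noise_deg_rms", "voltage_noise_v",
                     "trial_scatter_deg_sd", "head_shift_v", "blink_prob")

#' Read and validate a YAML run configuration
#'
#' Unknown keys anywhere in the file are rejected; the calibration
#' order must be 2, 3 or 4.
#'
#' @param path YAML file with optional blocks \code{geometry},
#'   \code{simulator}, \code{calibration}, \code{paths}.
#' @return the validated configuration list, with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  extra <- setdiff(names(cfg), names(.cfg_schema))
  if (length(extra))
    stop("unknown configuration block(s): ", paste(extra, collapse = ", "))
  for (blk in names(.cfg_schema)) {
    extra <- setdiff(names(cfg[[blk]]), .cfg_schema[[blk]])
    if (length(extra))
      stop("unknown key(s) in '", blk, "': ", paste(extra, collapse = ", "))
  }
  extra <- setdiff(names(cfg$simulator$noise), .cfg_noise_keys)
  if (length(extra))
    stop("unknown key(s) in 'simulator$noise': ",
         paste(extra, collapse = ", "))
  ord <- cfg$calibration$order
  if (!is.null(ord) && !ord %in% 2:4)
    stop("calibration order must be 2, 3 or 4 (got ", ord, ")")
  fo <- cfg$calibration$fit_on
  if (!is.null(fo) && !fo %in% c("mesh", "anchors"))
    stop("calibration fit_on must be 'mesh' or 'anchors'")
  cfg
}
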