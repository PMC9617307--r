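# Calibrated spectrogram container and image I/O.
#
# Display convention: row 1 is the top of the image; the regurgitant jet is
# drawn on one side of the zero-velocity baseline (MR jets are typically
# displayed below the baseline, i.e. at increasing row index).  Velocities are
# always reported as magnitudes.

#' Calibrated continuous-wave Doppler spectrogram
#'
#' Wraps a non-negative intensity grid (rows = velocity bins, columns = time
#' frames) with its physical axis calibration: seconds per column `dt`, m/s
#' per row `dv`, the row index of the zero-velocity baseline, and the side of
#' the baseline that carries the regurgitant jet.
#'
#' @param intensity Numeric matrix of non-negative intensities.
#' @param dt Seconds per column (> 0); encodes the strip recording speed.
#' @param dv m/s per row (> 0).
#' @param baseline_row Row index (1-based) of zero velocity.
#' @param jet_side `"below"` (jet at rows > baseline, the usual MR display) or
#'   `"above"`.
#' @return An object of class `"spectrogram"`.
#' @export
calibrate_pixels <- function(intensity, dt, dv, baseline_row,
                             jet_side = c("below", "above")) {
  jet_side <- match.arg(jet_side)
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    mrlap_error("`intensity` must be a numeric matrix", "mrlap_calibration_error")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    mrlap_error("intensities must be finite and non-negative", "mrlap_calibration_error")
  }
  stopifnot_scalar(dt, "dt", "mrlap_calibration_error")
  stopifnot_scalar(dv, "dv", "mrlap_calibration_error")
  if (dt <= 0 || dv <= 0) {
    mrlap_error("`dt` and `dv` must be > 0", "mrlap_calibration_error")
  }
  if (baseline_row < 1 || baseline_row > nrow(intensity)) {
    mrlap_error(sprintf("`baseline_row` = %s outside the grid (1..%d)",
                        format(baseline_row), nrow(intensity)),
                "mrlap_calibration_error")
  }
  structure(list(intensity = intensity, dt = dt, dv = dv,
                 baseline_row = as.integer(baseline_row), jet_side = jet_side),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("Spectrogram: %d velocity bins x %d frames, dt = %g s, dv = %g m/s\n",
              nrow(x$intensity), ncol(x$intensity), x$dt, x$dv))
  cat(sprintf("  baseline row %d, jet %s baseline; velocity span 0..%.2f m/s\n",
              x$baseline_row, x$jet_side, max(abs(jet_rows(x) - x$baseline_row)) * x$dv))
  invisible(x)
}

# Row indices on the jet side, ordered by increasing velocity magnitude.
#' @noRd
jet_rows <- function(spec) {
  if (spec$jet_side == "below") {
    seq(spec$baseline_row, nrow(spec$intensity))
  } else {
    seq(spec$baseline_row, 1L)
  }
}

# Velocity magnitude (m/s) of each row in jet_rows(spec).
#' @noRd
jet_velocities <- function(spec) {
  abs(jet_rows(spec) - spec$baseline_row) * spec$dv
}

#' Read and write spectrogram images with a calibration sidecar
#'
#' Images are single-channel PNG or TIFF (multi-channel input is converted to
#' luminance).  The sidecar is a small YAML file with keys `dt_s`, `dv_mps`,
#' `baseline_row` (1-based) and `jet_side`.
#'
#' @param image_path Path to a `.png`, `.tif` or `.tiff` file.
#' @param calib_path Path to the YAML calibration sidecar; defaults to the
#'   image path with extension replaced by `.yaml`.
#' @return A [calibrate_pixels] spectrogram.
#' @export
read_spectrogram <- function(image_path,
                             calib_path = sub("\\.[^.]+$", ".yaml", image_path)) {
  if (!file.exists(image_path)) {
    mrlap_error(sprintf("image file not found: %s", image_path), "mrlap_io_error")
  }
  if (!file.exists(calib_path)) {
    mrlap_error(sprintf("calibration sidecar not found: %s", calib_path), "mrlap_io_error")
  }
  ext <- tolower(sub(".*\\.", "", image_path))
  img <- switch(ext,
    png = png::readPNG(image_path),
    tif = ,
    tiff = tiff::readTIFF(image_path),
    mrlap_error(sprintf("unsupported image format: .%s", ext), "mrlap_io_error"))
  if (length(dim(img)) == 3L) {
    # Luminance conversion for RGB(A) input.
    img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  }
  calib <- yaml::read_yaml(calib_path)
  req <- c("dt_s", "dv_mps", "baseline_row", "jet_side")
  missing <- setdiff(req, names(calib))
  if (length(missing)) {
    mrlap_error(paste("calibration sidecar missing keys:",
                      paste(missing, collapse = ", ")), "mrlap_io_error")
  }
  calibrate_pixels(img, dt = calib$dt_s, dv = calib$dv_mps,
                   baseline_row = calib$baseline_row, jet_side = calib$jet_side)
}

#' @rdname read_spectrogram
#' @param spec A spectrogram to write.
#' @export
write_spectrogram <- function(spec, image_path,
                              calib_path = sub("\\.[^.]+$", ".yaml", image_path)) {
  stopifnot(inherits(spec, "spectrogram"))
  img <- pmin(pmax(spec$intensity, 0), 1)
  ext <- tolower(sub(".*\\.", "", image_path))
  switch(ext,
    png = png::writePNG(img, image_path),
    tif = ,
    tiff = tiff::writeTIFF(img, image_path),
    mrlap_error(sprintf("unsupported image format: .%s", ext), "mrlap_io_error"))
  yaml::write_yaml(list(dt_s = spec$dt, dv_mps = spec$dv,
                        baseline_row = spec$baseline_row,
                        jet_side = spec$jet_side), calib_path)
  invisible(c(image = image_path, calib = calib_path))
}
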