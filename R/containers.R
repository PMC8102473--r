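#' Linear intensity-to-density calibration
#'
#' HR-pQCT scanners store raw intensities; densitometry needs mg HA/cm^3. The
#' mapping is linear: `density = slope * intensity + intercept`.
#'
#' @param slope Density gain in (mg HA/cm^3) per intensity unit; must be > 0
#'   so the mapping is invertible.
#' @param intercept Density offset in mg HA/cm^3.
#' @return A `calibration` object.
#' @export
#' @examples
#' cal <- calibration(slope = 0.5, intercept = -100)
#' apply_calibration(800, cal)  # 300 mg HA/cm^3
calibration <- function(slope = 0.5, intercept = -100) {
  if (!is.numeric(slope) || length(slope) != 1 || !is.finite(slope) || slope <= 0) {
    stop_mcv("calibration slope must be a single positive number", "mcv_config_error")
  }
  if (!is.numeric(intercept) || length(intercept) != 1 || !is.finite(intercept)) {
    stop_mcv("calibration intercept must be a single finite number", "mcv_config_error")
  }
  structure(list(slope = slope, intercept = intercept), class = "mcv_calibration")
}

#' @rdname calibration
#' @param intensity Numeric intensities (any shape).
#' @param cal A `calibration` object.
#' @export
apply_calibration <- function(intensity, cal) {
  stopifnot(inherits(cal, "mcv_calibration"))
  cal$slope * intensity + cal$intercept
}

#' @rdname calibration
#' @param density Numeric densities in mg HA/cm^3.
#' @export
invert_calibration <- function(density, cal) {
  stopifnot(inherits(cal, "mcv_calibration"))
  (density - cal$intercept) / cal$slope
}

#' Calibrated HR-pQCT volume
#'
#' The pipeline's image currency: a 3D intensity grid (rows x cols x slices)
#' on an isotropic lattice, together with the voxel size and the linear
#' calibration that converts intensities to mg HA/cm^3.
#'
#' @param intensities 3D numeric array (rows, cols, slices).
#' @param voxel_size_mm Isotropic voxel edge length in mm (default 0.082, the
#'   scanner's native resolution).
#' @param calibration A [calibration()] object.
#' @param laterality `"left"` or `"right"`.
#' @param case_id Character identifier.
#' @return A `calibrated_volume` object.
#' @export
calibrated_volume <- function(intensities, voxel_size_mm = 0.082,
                              calibration = mcvbmd::calibration(),
                              laterality = "right", case_id = "case") {
  if (length(dim(intensities)) != 3) {
    stop_mcv("intensities must be a 3D array", "mcv_shape_error")
  }
  if (any(dim(intensities) < 1)) {
    stop_mcv("all volume dimensions must be >= 1", "mcv_shape_error")
  }
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0) {
    stop_mcv("voxel_size_mm must be > 0", "mcv_config_error")
  }
  if (!laterality %in% c("left", "right")) {
    stop_mcv("laterality must be 'left' or 'right'", "mcv_metadata_error")
  }
  structure(
    list(
      intensities = intensities,
      voxel_size_mm = voxel_size_mm,
      calibration = calibration,
      laterality = laterality,
      case_id = case_id
    ),
    class = "calibrated_volume"
  )
}

#' @export
print.calibrated_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<calibrated_volume '%s'> %dx%dx%d voxels @ %.3f mm, %s hand\n",
    x$case_id, d[1], d[2], d[3], x$voxel_size_mm, x$laterality
  ))
  cat(sprintf("  calibration: density = %.4g * I + %.4g mg HA/cm^3\n",
              x$calibration$slope, x$calibration$intercept))
  invisible(x)
}

#' Densities of a calibrated volume
#'
#' @param volume A [calibrated_volume()].
#' @return 3D array of densities in mg HA/cm^3.
#' @export
volume_density <- function(volume) {
  stopifnot(inherits(volume, "calibrated_volume"))
  apply_calibration(volume$intensities, volume$calibration)
}

#' Binary segmentation mask
#'
#' A {0,1} grid on the same lattice as its companion volume. Houses either an
#' expert annotation or a network prediction. `annotated_range` is the
#' half-open 0-based slice range `[first, last)` the expert annotated.
#'
#' @param values 3D array with values in {0, 1}.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param annotated_range Integer length-2 vector `[first, last)`; defaults to
#'   the full slice range.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(values, voxel_size_mm = 0.082, annotated_range = NULL) {
  if (length(dim(values)) != 3) {
    stop_mcv("mask values must be a 3D array", "mcv_shape_error")
  }
  if (!is_binary_array(values)) {
    stop_mcv("mask values must be strictly binary (0/1)", "mcv_mask_error")
  }
  ns <- dim(values)[3]
  annotated_range <- as.integer(annotated_range %||% c(0L, ns))
  if (length(annotated_range) != 2 || annotated_range[1] < 0 ||
      annotated_range[2] > ns || annotated_range[1] >= annotated_range[2]) {
    stop_mcv("annotated_range must be a valid half-open slice range", "mcv_range_error")
  }
  structure(
    list(
      values = array(as.numeric(values), dim = dim(values)),
      voxel_size_mm = voxel_size_mm,
      annotated_range = annotated_range
    ),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<binary_mask> %dx%dx%d voxels @ %.3f mm, %d foreground, slices [%d,%d)\n",
    d[1], d[2], d[3], x$voxel_size_mm, sum(x$values),
    x$annotated_range[1], x$annotated_range[2]
  ))
  invisible(x)
}

# Accept either a binary_mask or a raw array where masks are consumed.
mask_values <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$values else mask
}

volume_values <- function(volume) {
  if (inherits(volume, "calibrated_volume")) volume$intensities else volume
}
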