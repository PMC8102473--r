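#' @name postprocess
#' @title Post-processing: from network output to a clinically usable mask
#' @description
#' Inverts the pre-processing chain on a predicted mask: mirror left hands
#' back, remove interior holes (the density measurement needs a solid mask),
#' resample to the original in-plane resolution, and re-insert the slices
#' dropped before training.
NULL

#' Mirror a prediction back to the patient's true orientation
#'
#' Applies the column flip iff the case was flipped during pre-processing.
#'
#' @param mask [binary_mask()] or 3D binary array.
#' @param record The case's preprocess record.
#' @return Same container type as the input.
#' @export
flip_back <- function(mask, record) {
  if (is.null(record$was_flipped)) {
    stop_mcv("record does not say whether the case was flipped",
             "mcv_metadata_error")
  }
  if (!record$was_flipped) return(mask)
  if (inherits(mask, "binary_mask")) {
    mask$values <- flip_cols(mask$values)
    mask
  } else {
    flip_cols(mask)
  }
}

# slice-wise border flood fill: background connected to the slice border
# stays background, enclosed background becomes foreground.
flood_fill_slice <- function(sl) {
  bg <- !sl
  reach <- matrix(FALSE, nrow(sl), ncol(sl))
  reach[1, ] <- bg[1, ]
  reach[nrow(sl), ] <- bg[nrow(sl), ]
  reach[, 1] <- reach[, 1] | bg[, 1]
  reach[, ncol(sl)] <- reach[, ncol(sl)] | bg[, ncol(sl)]
  repeat {
    up <- rbind(reach[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, reach[-nrow(reach), , drop = FALSE])
    lf <- cbind(reach[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, reach[, -ncol(reach), drop = FALSE])
    new <- reach | (bg & (up | dn | lf | rt))
    if (identical(new, reach)) break
    reach <- new
  }
  sl | (bg & !reach)
}

#' Remove interior holes from a segmentation mask
#'
#' Interior cavities -- background components not connected to the slice
#' border, judged per slice in 2D to match the slice-wise annotation
#' workflow -- become foreground. A bounded morphological closing (disk of
#' radius `tol` voxels) first smooths the boundary and seals pinholes; the
#' slice-wise border flood fill then guarantees a solid mask. Open notches
#' that reach the exterior (cortical erosions) stay open. The operation is
#' monotone (output is a superset of the input), moves the outer boundary by
#' at most `tol` voxels, and is idempotent.
#'
#' @param mask [binary_mask()] or 3D binary array.
#' @param tol Maximum outward boundary movement in voxels (closing radius);
#'   default 1. `tol = 0` skips the smoothing and only flood-fills.
#' @return Same container type as the input.
#' @export
fill_holes <- function(mask, tol = 1) {
  vals <- mask_values(mask)
  if (!is_binary_array(vals)) {
    stop_mcv("fill_holes expects a binary mask", "mcv_mask_error")
  }
  d <- dim(vals)
  out <- vals
  brush <- if (tol > 0) EBImage::makeBrush(2 * tol + 1, shape = "disc") else NULL
  for (z in seq_len(d[3])) {
    sl <- vals[, , z] > 0
    if (!any(sl)) next
    if (!is.null(brush)) {
      cl <- EBImage::closing(EBImage::Image(sl * 1), brush) > 0.5
      sl <- sl | matrix(cl, d[1], d[2])
    }
    out[, , z] <- flood_fill_slice(sl) * 1
  }
  if (inherits(mask, "binary_mask")) {
    mask$values <- out
    mask
  } else {
    out
  }
}

#' Restore a prediction to the original in-plane resolution
#'
#' Upsamples the (cropped-grid) prediction back to the original in-plane
#' shape recorded during pre-processing, with trilinear interpolation and a
#' 0.5 threshold; the slice count becomes the annotated slice count. Some
#' boundary roughness from the upsampling is expected and visible in
#' rendered overlays.
#'
#' @param mask Prediction at the network grid ([binary_mask()] or array).
#' @param record The case's preprocess record (needs `original_shape`,
#'   `annotated_range`, `resize_factors`).
#' @return [binary_mask()] at the original in-plane resolution and the
#'   annotated slice count.
#' @export
restore_full_resolution <- function(mask, record) {
  if (is.null(record$original_shape) || is.null(record$annotated_range)) {
    stop_mcv("record lacks original_shape/annotated_range", "mcv_metadata_error")
  }
  vals <- mask_values(mask)
  n_ann <- record$annotated_range[2] - record$annotated_range[1]
  target <- c(record$original_shape[1:2], n_ann)
  up <- resample_linear(vals, target)
  binary_mask((up > 0.5) * 1,
              voxel_size_mm = if (inherits(mask, "binary_mask")) mask$voxel_size_mm else 0.082)
}

#' Re-insert the slices dropped before training
#'
#' Pads the restored prediction with all-zero slices outside the annotated
#' range so the output has the original slice count.
#'
#' @param mask Prediction at original in-plane resolution, annotated slices
#'   only.
#' @param record The case's preprocess record.
#' @return [binary_mask()] with the original grid shape; slices outside the
#'   annotated range are all-zero.
#' @export
restore_dropped_slices <- function(mask, record) {
  vals <- mask_values(mask)
  d <- dim(vals)
  rng <- record$annotated_range
  full <- record$original_shape
  if (d[3] != rng[2] - rng[1] || rng[2] > full[3]) {
    stop_mcv("annotated range inconsistent with original shape",
             "mcv_range_error")
  }
  out <- array(0, dim = full)
  out[, , (rng[1] + 1):rng[2]] <- vals
  binary_mask(out,
              voxel_size_mm = if (inherits(mask, "binary_mask")) mask$voxel_size_mm else 0.082,
              annotated_range = rng)
}

#' Full post-processing chain for one prediction
#'
#' binarize -> flip back -> fill holes -> restore resolution -> restore
#' dropped slices. Output has exactly the original grid shape of the case.
#'
#' @param prob Probability grid at the network input shape.
#' @param record The case's preprocess record.
#' @param threshold Binarization threshold (default 0.5).
#' @param tol Hole-filling boundary tolerance (voxels).
#' @param voxel_size_mm Voxel size stamped on the result.
#' @return [binary_mask()] on the original grid.
#' @export
postprocess_prediction <- function(prob, record, threshold = 0.5, tol = 1,
                                   voxel_size_mm = 0.082) {
  m <- binarize(prob, threshold)
  m <- flip_back(m, record)
  m <- fill_holes(m, tol = tol)
  m <- binary_mask(m, voxel_size_mm = voxel_size_mm)
  m <- restore_full_resolution(m, record)
  restore_dropped_slices(m, record)
}
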