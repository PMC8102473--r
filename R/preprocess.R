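#' @name preprocess
#' @title Pre-processing chain for network training
#' @description
#' Maps a raw (volume, annotation) pair onto the network input grid:
#' the un-annotated slices are dropped, left hands are mirrored to a
#' canonical right-hand orientation, the case is resampled to a common shape
#' (512 x 512 x 80 at full scale), and intensities are standardized with the
#' training-set mean and variance. Every step records what is needed to map
#' a prediction back to the original grid.
NULL

# Separable linear resampling of a 3D array to `target`. Output sample i maps
# to input coordinate (i + 0.5) * n_in / n_out - 0.5 (pixel-area convention),
# clamped at the borders; weights sum to one so constants are preserved.
resample_linear <- function(arr, target) {
  d <- dim(arr)
  target <- as.integer(target)
  interp_matrix <- function(n_in, n_out) {
    if (n_in == n_out) return(diag(n_out))
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pos <- pmin(pmax(pos, 0), n_in - 1)
    lo <- floor(pos)
    frac <- pos - lo
    hi <- pmin(lo + 1, n_in - 1)
    m <- matrix(0, n_out, n_in)
    m[cbind(seq_len(n_out), lo + 1)] <- 1 - frac
    m[cbind(seq_len(n_out), hi + 1)] <-
      m[cbind(seq_len(n_out), hi + 1)] + frac
    m
  }
  # axis 1 (rows)
  m1 <- interp_matrix(d[1], target[1])
  arr <- array(m1 %*% matrix(arr, d[1], d[2] * d[3]),
               dim = c(target[1], d[2], d[3]))
  # axis 2 (cols)
  m2 <- interp_matrix(d[2], target[2])
  arr <- aperm(arr, c(2, 1, 3))
  arr <- array(m2 %*% matrix(arr, d[2], target[1] * d[3]),
               dim = c(target[2], target[1], d[3]))
  arr <- aperm(arr, c(2, 1, 3))
  # axis 3 (slices)
  m3 <- interp_matrix(d[3], target[3])
  arr <- aperm(arr, c(3, 1, 2))
  arr <- array(m3 %*% matrix(arr, d[3], target[1] * target[2]),
               dim = c(target[3], target[1], target[2]))
  aperm(arr, c(2, 3, 1))
}

new_preprocess_record <- function(original_shape, annotated_range,
                                  was_flipped = FALSE,
                                  resize_factors = c(1, 1, 1),
                                  normalization_stats_id = NA_character_) {
  structure(
    list(original_shape = as.integer(original_shape),
         annotated_range = as.integer(annotated_range),
         was_flipped = was_flipped,
         resize_factors = resize_factors,
         normalization_stats_id = normalization_stats_id),
    class = "preprocess_record"
  )
}

#' Crop a case to its annotated slice range
#'
#' Drops all slices outside the annotation's VOI from both the volume and
#' the rasterized expert mask, and opens the [preprocess record] that later
#' restores the prediction to the original grid.
#'
#' @param volume A [calibrated_volume()].
#' @param annotation A [contour_annotation()] whose VOI lies within the
#'   volume's slice range.
#' @return List with `volume` (cropped array-backed [calibrated_volume()]),
#'   `mask` (cropped [binary_mask()]) and `record`.
#' @export
extract_annotated_region <- function(volume, annotation) {
  stopifnot(inherits(volume, "calibrated_volume"),
            inherits(annotation, "contour_annotation"))
  d <- dim(volume$intensities)
  voi <- annotation$voi
  if (voi[1] < 0 || voi[2] > d[3]) {
    stop_mcv(sprintf("VOI [%d,%d) lies outside the %d-slice volume",
                     voi[1], voi[2], d[3]), "mcv_range_error")
  }
  mask <- contour_to_mask(annotation, d, voxel_size_mm = volume$voxel_size_mm)
  zsel <- seq(voi[1] + 1L, voi[2])
  cropped_vol <- volume
  cropped_vol$intensities <- volume$intensities[, , zsel, drop = FALSE]
  cropped_mask <- binary_mask(mask$values[, , zsel, drop = FALSE],
                              voxel_size_mm = mask$voxel_size_mm)
  record <- new_preprocess_record(d, voi)
  list(volume = cropped_vol, mask = cropped_mask, record = record)
}

#' Resample a case to the network input shape
#'
#' Trilinear interpolation for the intensities; the mask is interpolated the
#' same way and re-binarized at 0.5, which restores a strictly binary mask
#' with smoother boundaries than nearest-neighbour resampling at 3x
#' downscale. At full scale the target is 512 x 512 x 80; scaled-down
#' targets are first-class for desk-size experiments.
#'
#' @param volume A [calibrated_volume()] (annotated region already cropped).
#' @param mask The matching [binary_mask()].
#' @param record The case's preprocess record (updated in the return value).
#' @param target_shape Integer (rows, cols, slices), default c(512, 512, 80).
#' @return List with resized `volume`, `mask` and updated `record`.
#' @export
resize_case <- function(volume, mask, record,
                        target_shape = c(512L, 512L, 80L)) {
  target_shape <- as.integer(target_shape)
  if (any(target_shape < 1)) {
    stop_mcv("target_shape entries must be >= 1", "mcv_shape_error")
  }
  d <- dim(volume$intensities)
  assert_same_shape(volume$intensities, mask_values(mask), "volume and mask")
  volume$intensities <- resample_linear(volume$intensities, target_shape)
  mvals <- resample_linear(mask_values(mask), target_shape)
  mask <- binary_mask((mvals > 0.5) * 1, voxel_size_mm = mask$voxel_size_mm)
  record$resize_factors <- target_shape / d
  record$resized_from <- d
  list(volume = volume, mask = mask, record = record)
}

#' Mirror left hands to the canonical right-hand orientation
#'
#' Flips volume and mask along the column axis iff `laterality == "left"`,
#' so the network always sees right hands; the flag is recorded for the
#' inverse flip in post-processing. Applying the flip twice is the identity.
#'
#' @param volume,mask The case (any stage of the chain).
#' @param record Preprocess record; `was_flipped` is set here.
#' @param laterality `"left"` or `"right"`; anything else is a metadata error.
#' @return List with `volume`, `mask`, `record`.
#' @export
flip_if_left <- function(volume, mask, record, laterality = volume$laterality) {
  if (!identical(laterality, "left") && !identical(laterality, "right")) {
    stop_mcv("unknown laterality; expected 'left' or 'right'",
             "mcv_metadata_error")
  }
  if (identical(laterality, "left")) {
    volume$intensities <- flip_cols(volume$intensities)
    mask$values <- flip_cols(mask$values)
    record$was_flipped <- TRUE
  } else {
    record$was_flipped <- FALSE
  }
  list(volume = volume, mask = mask, record = record)
}

flip_cols <- function(arr) {
  arr[, rev(seq_len(dim(arr)[2])), , drop = FALSE]
}

#' Training-set intensity normalization
#'
#' Computes the global mean and variance over all voxels of the training
#' volumes (never validation or test data) and standardizes volumes to zero
#' mean, unit variance with them. `provenance` must name the split the stats
#' came from; computing stats on a whole cohort before splitting defeats the
#' held-out evaluation, so provenance values suggesting that ("all",
#' "cohort", "full") raise a warning.
#'
#' @param volumes List of [calibrated_volume()] objects or 3D arrays
#'   (training split only).
#' @param provenance Identifier of the training split the stats derive from.
#' @return A `normalization_stats` object with `mean`, `variance`,
#'   `provenance` and a content id.
#' @export
compute_norm_stats <- function(volumes, provenance) {
  if (missing(provenance)) {
    stop_mcv("normalization stats need a provenance naming the training split",
             "mcv_provenance_error")
  }
  if (tolower(provenance) %in% c("all", "cohort", "full", "everything")) {
    rlang::warn(paste0(
      "normalization stats computed on '", provenance, "': stats must come ",
      "from the training split only or information leaks into evaluation"
    ), class = "mcv_leakage_warning")
  }
  n_tot <- 0
  s1 <- 0
  s2 <- 0
  for (v in volumes) {
    x <- volume_values(v)
    n_tot <- n_tot + length(x)
    s1 <- s1 + sum(x)
    s2 <- s2 + sum(x^2)
  }
  if (n_tot == 0) stop_mcv("no voxels to compute stats from", "mcv_config_error")
  mu <- s1 / n_tot
  va <- s2 / n_tot - mu^2
  if (va <= 0) {
    stop_mcv("zero variance in training data; normalization undefined",
             "mcv_degenerate_error")
  }
  structure(
    list(mean = mu, variance = va, provenance = provenance,
         id = substr(object_hash(list(mu, va, provenance)), 1, 12)),
    class = "normalization_stats"
  )
}

#' @rdname compute_norm_stats
#' @param volume A [calibrated_volume()] or 3D array to standardize.
#' @param stats A `normalization_stats` object.
#' @return `normalize_volume` returns the input with intensities replaced by
#'   `(x - mean) / sqrt(variance)` (same container type as given).
#' @export
normalize_volume <- function(volume, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  if (stats$variance <= 0) {
    stop_mcv("stats variance must be positive", "mcv_degenerate_error")
  }
  z <- (volume_values(volume) - stats$mean) / sqrt(stats$variance)
  if (inherits(volume, "calibrated_volume")) {
    volume$intensities <- z
    volume
  } else {
    z
  }
}

#' Full pre-processing chain for one case
#'
#' crop to VOI -> mirror left hands -> resample to the network shape.
#' Normalization is applied separately once training-set stats exist
#' (the chain is crop, flip, resize, normalize; flip and resize commute, and
#' normalizing after resizing makes the stats match what the network sees).
#'
#' @param volume,annotation The raw case.
#' @param target_shape Network input shape.
#' @return List with `x` (resized volume), `y` (resized mask), `record`.
#' @export
preprocess_case <- function(volume, annotation,
                            target_shape = c(512L, 512L, 80L)) {
  st <- extract_annotated_region(volume, annotation)
  st2 <- flip_if_left(st$volume, st$mask, st$record,
                      laterality = volume$laterality)
  st3 <- resize_case(st2$volume, st2$mask, st2$record, target_shape)
  list(x = st3$volume, y = st3$mask, record = st3$record)
}
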