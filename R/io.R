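#' Slice-wise contour annotation
#'
#' The exchange form for expert (or predicted) segmentations: one closed
#' polygon per object per slice, plus the volume-of-interest (VOI) slice
#' range. Coordinate convention (fixed repo-wide): voxel indices are 0-based;
#' slice ranges are half-open `[first, last)`; polygon vertices live in
#' continuous voxel coordinates where integer coordinates are voxel centres,
#' ordered (row, col). Polygons are implicitly closed.
#'
#' @param polygons List of records, each `list(slice = <0-based index>,
#'   vertices = <n x 2 matrix of (row, col)>)`.
#' @param voi Integer length-2 half-open slice range `[start, end)`.
#' @param laterality `"left"` or `"right"`.
#' @param case_id Character identifier.
#' @return A `contour_annotation` object.
#' @export
contour_annotation <- function(polygons = list(), voi, laterality = "right",
                               case_id = "case") {
  voi <- as.integer(voi)
  if (length(voi) != 2 || voi[1] < 0 || voi[1] >= voi[2]) {
    stop_mcv("voi must be a valid half-open slice range", "mcv_range_error")
  }
  for (p in polygons) {
    if (is.null(p$slice) || is.null(p$vertices)) {
      stop_mcv("each polygon needs $slice and $vertices", "mcv_config_error")
    }
    if (p$slice < voi[1] || p$slice >= voi[2]) {
      stop_mcv(
        sprintf("polygon on slice %d lies outside the VOI [%d,%d)",
                p$slice, voi[1], voi[2]),
        "mcv_range_error"
      )
    }
    if (!is.matrix(p$vertices) || ncol(p$vertices) != 2 || nrow(p$vertices) < 3) {
      stop_mcv("polygon vertices must be an n x 2 matrix with n >= 3",
               "mcv_geometry_error")
    }
  }
  structure(
    list(polygons = polygons, voi = voi, laterality = laterality,
         case_id = case_id),
    class = "contour_annotation"
  )
}

#' @export
print.contour_annotation <- function(x, ...) {
  cat(sprintf("<contour_annotation '%s'> %d polygon(s), VOI [%d,%d), %s hand\n",
              x$case_id, length(x$polygons), x$voi[1], x$voi[2], x$laterality))
  invisible(x)
}

# ---------------------------------------------------------------------------
# contour <-> mask conversion

#' Rasterize a contour annotation to a binary mask
#'
#' Applies the voxel-centre rule slice by slice: a voxel is foreground iff
#' its centre lies strictly inside one of the slice's polygons (centres
#' exactly on a polygon edge are background). Slices outside the VOI are
#' all-zero and the result's `annotated_range` is the VOI.
#'
#' @param annotation A [contour_annotation()].
#' @param grid_shape Integer (rows, cols, slices) of the target grid.
#' @param voxel_size_mm Voxel size for the resulting mask.
#' @return A [binary_mask()].
#' @export
contour_to_mask <- function(annotation, grid_shape, voxel_size_mm = 0.082) {
  stopifnot(inherits(annotation, "contour_annotation"))
  grid_shape <- as.integer(grid_shape)
  if (annotation$voi[2] > grid_shape[3]) {
    stop_mcv("annotation VOI extends past the grid's slice range", "mcv_range_error")
  }
  vals <- array(0, dim = grid_shape)
  for (p in annotation$polygons) {
    vr <- p$vertices[, 1]
    vc <- p$vertices[, 2]
    # drop an explicit closing vertex
    nv <- length(vr)
    if (nv > 1 && vr[1] == vr[nv] && vc[1] == vc[nv]) {
      vr <- vr[-nv]; vc <- vc[-nv]
    }
    if (any(vr < -0.5 | vr > grid_shape[1] - 0.5 |
            vc < -0.5 | vc > grid_shape[2] - 0.5)) {
      stop_mcv("polygon vertices fall outside the grid", "mcv_geometry_error")
    }
    if (polygon_self_intersects_cpp(vr, vc)) {
      stop_mcv(sprintf("self-intersecting polygon on slice %d", p$slice),
               "mcv_geometry_error")
    }
    sl <- rasterize_polygon_cpp(vr, vc, grid_shape[1], grid_shape[2])
    z <- p$slice + 1L
    vals[, , z] <- pmax(vals[, , z], sl * 1)
  }
  binary_mask(vals, voxel_size_mm = voxel_size_mm,
              annotated_range = annotation$voi)
}

# 4-connected component labelling of a logical matrix via label propagation.
label_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[m] <- seq_len(sum(m))
  idx <- which(m)
  if (length(idx) == 0) return(lab)
  lab[m] <- seq_along(idx)
  repeat {
    shifted <- lab
    up <- rbind(lab[-1, , drop = FALSE], 0L)
    dn <- rbind(0L, lab[-nrow(lab), , drop = FALSE])
    lf <- cbind(lab[, -1, drop = FALSE], 0L)
    rt <- cbind(0L, lab[, -ncol(lab), drop = FALSE])
    nb <- pmax(up, dn, lf, rt)
    new <- lab
    new[m] <- pmax(lab[m], nb[m])
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# Crack-boundary tracing of the outer boundary of one 4-connected component.
# `comp` is a logical matrix; returns an n x 2 matrix of (row, col) vertices
# at half-integer coordinates, foreground kept on the right of travel.
trace_outer_boundary <- function(comp) {
  pix <- which(comp, arr.ind = TRUE)
  # start: topmost (min row), then leftmost fg pixel; 0-based centre coords
  o <- order(pix[, 1], pix[, 2])
  sr <- pix[o[1], 1] - 1
  sc <- pix[o[1], 2] - 1
  at <- function(r, c) {
    r >= 0 && r < nrow(comp) && c >= 0 && c < ncol(comp) && comp[r + 1, c + 1]
  }
  # walk corners (half-integer coords); direction in (drow, dcol)
  start <- c(sr - 0.5, sc - 0.5)
  dir <- c(0, 1) # along the top edge, +col
  pos <- start
  verts <- list()
  repeat {
    verts[[length(verts) + 1L]] <- pos
    pos <- pos + dir
    # pixels around the new corner, relative to direction of travel:
    # right(d) = (dcol, -drow) in (row, col) with row increasing downward
    rightd <- c(dir[2], -dir[1])
    fr <- pos + 0.5 * dir + 0.5 * rightd # front-right pixel centre
    fl <- pos + 0.5 * dir - 0.5 * rightd # front-left pixel centre
    if (!at(fr[1], fr[2])) {
      dir <- rightd
    } else if (!at(fl[1], fl[2])) {
      # straight on
    } else {
      dir <- -rightd
    }
    if (all(pos == start) && identical(dir, c(0, 1))) break
  }
  vm <- do.call(rbind, verts)
  # compress collinear runs
  keep <- rep(TRUE, nrow(vm))
  n <- nrow(vm)
  for (i in seq_len(n)) {
    a <- vm[if (i == 1) n else i - 1, ]
    b <- vm[i, ]
    cc <- vm[if (i == n) 1 else i + 1, ]
    if ((b[1] - a[1]) * (cc[2] - b[2]) == (b[2] - a[2]) * (cc[1] - b[1])) {
      keep[i] <- FALSE
    }
  }
  vm[keep, , drop = FALSE]
}

#' Trace contour polygons from a binary mask
#'
#' For every slice inside the mask's annotated range, traces one closed
#' polygon along the outer crack boundary (the polyline between foreground
#' and background voxels, vertices at half-integer voxel coordinates) of each
#' 4-connected foreground component. Interior holes are not contoured; the
#' post-processing fills them anyway. Because the traced polygon is the exact
#' region boundary of the voxel set, `contour_to_mask(mask_to_contour(m))`
#' reproduces `m` exactly for masks whose components are simply connected.
#'
#' @param mask A [binary_mask()] (or 3D binary array).
#' @param laterality,case_id Metadata carried into the annotation.
#' @return A [contour_annotation()]; an all-zero mask yields an annotation
#'   with zero polygons and VOI equal to the mask's annotated range.
#' @export
mask_to_contour <- function(mask, laterality = "right", case_id = "case") {
  vals <- mask_values(mask)
  if (!is_binary_array(vals)) {
    stop_mcv("mask must be strictly binary", "mcv_mask_error")
  }
  rng <- if (inherits(mask, "binary_mask")) mask$annotated_range else c(0L, dim(vals)[3])
  polys <- list()
  for (z in seq(rng[1], rng[2] - 1)) {
    sl <- vals[, , z + 1] > 0
    if (!any(sl)) next
    lab <- label_components(sl)
    for (lv in setdiff(unique(as.vector(lab)), 0L)) {
      comp <- lab == lv
      vm <- trace_outer_boundary(comp)
      polys[[length(polys) + 1L]] <- list(slice = z, vertices = vm)
    }
  }
  contour_annotation(polys, voi = rng, laterality = laterality,
                     case_id = case_id)
}

# ---------------------------------------------------------------------------
# volume / mask file I/O

sidecar_path <- function(path) {
  sub("(\\.nii\\.gz|\\.nii|\\.mha)$", ".json", path)
}

infer_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) return("nifti")
  if (grepl("\\.mha$", path)) return("mha")
  stop_mcv(sprintf("unknown volume format for '%s' (expect .nii, .nii.gz or .mha)",
                   path), "mcv_format_error")
}

check_writable <- function(path) {
  d <- dirname(path)
  if (!dir.exists(d) || file.access(d, 2) != 0) {
    stop_mcv(sprintf("directory '%s' is not writable", d), "mcv_io_error")
  }
}

write_mha <- function(arr, voxel_size_mm, path) {
  d <- dim(arr)
  hdr <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g\n",
            voxel_size_mm, voxel_size_mm, voxel_size_mm),
    "ElementType = MET_DOUBLE\n",
    "ElementDataFile = LOCAL\n"
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop_mcv("corrupt MetaImage header", "mcv_format_error")
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    if (length(kv) == 2) hdr[[kv[1]]] <- kv[2]
    if (identical(kv[1], "ElementDataFile")) break
  }
  if (!identical(hdr$ElementType, "MET_DOUBLE") ||
      !identical(hdr$ElementDataFile, "LOCAL")) {
    stop_mcv("unsupported MetaImage variant (need MET_DOUBLE, LOCAL data)",
             "mcv_format_error")
  }
  d <- as.integer(strsplit(hdr$DimSize, " ")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, " ")[[1]])
  vals <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  list(arr = array(vals, dim = d), voxel_size_mm = sp[1])
}

#' Read and write calibrated volumes
#'
#' Volumes travel as NIfTI (`.nii` / `.nii.gz`, via RNifti) or uncompressed
#' MetaImage (`.mha`). Calibration, laterality and case id do not fit either
#' header cleanly, so they are stored in a JSON sidecar next to the image
#' (same stem, `.json`); a missing sidecar on read is an error naming the
#' expected file. Round-trips preserve grid values exactly.
#'
#' @param volume A [calibrated_volume()].
#' @param path Destination/source path; format inferred from extension.
#' @return `read_volume` returns a [calibrated_volume()]; `write_volume`
#'   returns `path` invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "calibrated_volume"))
  fmt <- infer_format(path)
  check_writable(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(volume$intensities,
                           pixdim = rep(volume$voxel_size_mm, 3))
    RNifti::writeNifti(img, path)
  } else {
    write_mha(volume$intensities, volume$voxel_size_mm, path)
  }
  jsonlite::write_json(
    list(kind = "calibrated_volume",
         calibration = list(slope = volume$calibration$slope,
                            intercept = volume$calibration$intercept),
         voxel_size_mm = volume$voxel_size_mm,
         laterality = volume$laterality,
         case_id = volume$case_id),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop_mcv(sprintf("no such file: '%s'", path), "mcv_io_error")
  }
  fmt <- infer_format(path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop_mcv(sprintf("missing calibration sidecar '%s'", sc), "mcv_format_error")
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
    vs <- RNifti::pixdim(img)[1]
  } else {
    mh <- read_mha(path)
    arr <- mh$arr
    vs <- mh$voxel_size_mm
  }
  calibrated_volume(
    arr, voxel_size_mm = meta$voxel_size_mm %||% vs,
    calibration = calibration(meta$calibration$slope, meta$calibration$intercept),
    laterality = meta$laterality %||% "right",
    case_id = meta$case_id %||% "case"
  )
}

#' Read and write binary masks
#'
#' Same formats and sidecar convention as [write_volume()]; the sidecar
#' stores the annotated slice range instead of a calibration.
#'
#' @param mask A [binary_mask()].
#' @param path Destination/source path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  fmt <- infer_format(path)
  check_writable(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(mask$values, pixdim = rep(mask$voxel_size_mm, 3))
    RNifti::writeNifti(img, path)
  } else {
    write_mha(mask$values, mask$voxel_size_mm, path)
  }
  jsonlite::write_json(
    list(kind = "binary_mask",
         voxel_size_mm = mask$voxel_size_mm,
         annotated_range = mask$annotated_range),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    stop_mcv(sprintf("no such file: '%s'", path), "mcv_io_error")
  }
  fmt <- infer_format(path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop_mcv(sprintf("missing mask sidecar '%s'", sc), "mcv_format_error")
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
  } else {
    arr <- read_mha(path)$arr
  }
  binary_mask(arr, voxel_size_mm = meta$voxel_size_mm,
              annotated_range = meta$annotated_range)
}

#' Read and write contour annotations as JSON
#'
#' The documented contour exchange format: a JSON object with `case_id`,
#' `laterality`, `voi` (half-open 0-based slice range) and `slices`, a list
#' of records each holding `slice` and parallel `rows`/`cols` vertex arrays
#' in continuous voxel coordinates.
#'
#' @param annotation A [contour_annotation()].
#' @param path JSON file path.
#' @export
write_contours <- function(annotation, path) {
  stopifnot(inherits(annotation, "contour_annotation"))
  check_writable(path)
  recs <- lapply(annotation$polygons, function(p) {
    list(slice = p$slice, rows = p$vertices[, 1], cols = p$vertices[, 2])
  })
  jsonlite::write_json(
    list(case_id = annotation$case_id, laterality = annotation$laterality,
         voi = annotation$voi, slices = recs),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) {
    stop_mcv(sprintf("no such file: '%s'", path), "mcv_io_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  polys <- lapply(obj$slices, function(r) {
    list(slice = as.integer(r$slice),
         vertices = cbind(as.numeric(r$rows), as.numeric(r$cols)))
  })
  contour_annotation(polys, voi = obj$voi, laterality = obj$laterality,
                     case_id = obj$case_id)
}
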