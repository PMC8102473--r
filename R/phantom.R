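#' Specification of a synthetic metacarpal phantom
#'
#' Describes a calibrated HR-pQCT-like volume of a single metacarpal: a
#' tapering tube with a dense cortical shell and a lower-density trabecular
#' interior, swept along a gently curved axis through a soft-tissue
#' background. Optional cortical erosions (arthritis-like breaks in the
#' shell), nearby distractor bones, additive Gaussian noise in density units,
#' and a linear intensity/density calibration complete the emulation.
#'
#' The geometry model is a swept disk: slice `z` of the bone is the disk of
#' radius `r(z)` around the (possibly laterally displaced) axis centre, the
#' cortical shell being the outer `shell_thickness_mm` annulus of that disk.
#' A voxel belongs to a region iff its centre lies inside the continuous
#' region, which makes every geometric quantity checkable against a
#' brute-force point-in-region count.
#'
#' @param grid_shape Integer (rows, cols, slices). Clinical scans have
#'   200-320 slices; the in-plane default of 128 voxels (10.5 mm field of
#'   view at 82 um) keeps desk-scale work tractable while the geometry is
#'   resolution-independent.
#' @param voxel_size_mm Isotropic voxel size (default 0.082).
#' @param cortical_density,trabecular_density,background_density Class
#'   densities in mg HA/cm^3; must satisfy cortical > trabecular >
#'   background >= 0.
#' @param shell_thickness_mm Cortical shell thickness; must be smaller than
#'   the smallest bone radius.
#' @param bone_radius_mm Either a scalar base radius (a linear taper towards
#'   the distal end is applied, see `taper`) or a full per-slice radius
#'   profile of length `grid_shape[3]`.
#' @param taper Fractional radius reduction from proximal to distal end when
#'   `bone_radius_mm` is scalar (default 0.25).
#' @param axis_curvature_mm Amplitude of the lateral (column-direction)
#'   sinusoidal displacement of the bone axis.
#' @param n_erosions Number of cortical erosions carved into the shell.
#' @param erosion_radius_mm Radius of each (spherical) erosion.
#' @param n_distractors Number of parallel non-target bones placed beside the
#'   target (they receive bone densities but are never in the mask).
#' @param noise_sigma Additive Gaussian noise SD in density units.
#' @param laterality `"left"` or `"right"`; a left phantom is the exact
#'   column mirror of the right phantom generated from the same seed.
#' @param annotated_range Half-open 0-based slice range the virtual expert
#'   annotated; emulates the stopping rule at the distal narrowing. Default:
#'   the proximal 80% of the slices.
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 250L),
                         voxel_size_mm = 0.082,
                         cortical_density = 750,
                         trabecular_density = 180,
                         background_density = 30,
                         shell_thickness_mm = 0.6,
                         bone_radius_mm = 3.5,
                         taper = 0.25,
                         axis_curvature_mm = 0.5,
                         n_erosions = 0L,
                         erosion_radius_mm = 0.5,
                         n_distractors = 1L,
                         noise_sigma = 25,
                         laterality = "right",
                         annotated_range = NULL,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    stop_mcv("grid_shape must be three positive integers", "mcv_config_error")
  }
  if (!(cortical_density > trabecular_density &&
        trabecular_density > background_density && background_density >= 0)) {
    stop_mcv(
      "densities must satisfy cortical > trabecular > background >= 0",
      "mcv_config_error"
    )
  }
  ns <- grid_shape[3]
  if (length(bone_radius_mm) == 1) {
    z <- seq(0, 1, length.out = ns)
    radius_profile <- bone_radius_mm * (1 - taper * z)
  } else if (length(bone_radius_mm) == ns) {
    radius_profile <- as.numeric(bone_radius_mm)
  } else {
    stop_mcv("bone_radius_mm must be scalar or one value per slice", "mcv_config_error")
  }
  if (any(radius_profile <= 0)) {
    stop_mcv("bone radius profile must be strictly positive", "mcv_config_error")
  }
  if (shell_thickness_mm >= min(radius_profile)) {
    stop_mcv("shell_thickness_mm must be below the smallest bone radius", "mcv_config_error")
  }
  if (!laterality %in% c("left", "right")) {
    stop_mcv("laterality must be 'left' or 'right'", "mcv_metadata_error")
  }
  annotated_range <- as.integer(annotated_range %||% c(0L, ceiling(0.8 * ns)))
  if (annotated_range[1] < 0 || annotated_range[2] > ns ||
      annotated_range[1] >= annotated_range[2]) {
    stop_mcv("annotated_range must lie within [0, slices)", "mcv_range_error")
  }
  structure(
    list(
      grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
      cortical_density = cortical_density,
      trabecular_density = trabecular_density,
      background_density = background_density,
      shell_thickness_mm = shell_thickness_mm,
      radius_profile_mm = radius_profile,
      axis_curvature_mm = axis_curvature_mm,
      n_erosions = as.integer(n_erosions),
      erosion_radius_mm = erosion_radius_mm,
      n_distractors = as.integer(n_distractors),
      noise_sigma = noise_sigma,
      laterality = laterality,
      annotated_range = annotated_range,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# Axis centre (row, col) per slice in continuous 0-based voxel coordinates,
# for the canonical right-hand orientation.
phantom_axis <- function(spec) {
  d <- spec$grid_shape
  ns <- d[3]
  z01 <- if (ns > 1) seq(0, 1, length.out = ns) else 0.5
  curve_vox <- spec$axis_curvature_mm / spec$voxel_size_mm
  list(
    row = rep((d[1] - 1) / 2, ns),
    col = (d[2] - 1) / 2 + curve_vox * sin(pi * z01)
  )
}

#' Generate a synthetic calibrated metacarpal phantom
#'
#' Produces a [calibrated_volume()] and its ground-truth [binary_mask()] from
#' a [phantom_spec()]. The mask marks exactly the target bone (cortical shell
#' plus trabecular interior); distractor bones and eroded voxels inside the
#' bone outline keep the annotated bone region in the mask but carry
#' background density, so erosions create exactly the kind of shell break
#' that can punch holes into an imperfect automatic segmentation.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([calibrated_volume()]), `mask`
#'   ([binary_mask()]), and `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 32), seed = 7))
#' ph$volume
#' sum(ph$mask$values) > 0
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vs <- spec$voxel_size_mm
  axis <- phantom_axis(spec)
  r_vox <- spec$radius_profile_mm / vs
  shell_vox <- spec$shell_thickness_mm / vs

  # geometry must fit the in-plane field of view
  max_reach_col <- max(abs(axis$col - (d[2] - 1) / 2) + r_vox)
  if (max(r_vox) > (d[1] - 1) / 2 || max_reach_col > (d[2] - 1) / 2) {
    stop_mcv(
      "bone radius plus axis curvature exceeds the in-plane field of view",
      "mcv_geometry_error"
    )
  }

  rows <- seq_len(d[1]) - 1
  cols <- seq_len(d[2]) - 1

  density <- array(spec$background_density, dim = d)
  mask <- array(0, dim = d)

  paint_tube <- function(density, mask, axis_row, axis_col, r_vox, target) {
    for (z in seq_len(d[3])) {
      dr2 <- (rows - axis_row[z])^2
      dc2 <- (cols - axis_col[z])^2
      dist <- sqrt(outer(dr2, dc2, `+`))
      inside <- dist <= r_vox[z]
      if (!any(inside)) next
      trab <- dist <= (r_vox[z] - shell_vox)
      sl <- density[, , z]
      sl[inside] <- spec$cortical_density
      sl[trab] <- spec$trabecular_density
      density[, , z] <- sl
      if (target) mask[, , z][inside] <- 1
    }
    list(density = density, mask = mask)
  }

  res <- paint_tube(density, mask, axis$row, axis$col, r_vox, target = TRUE)
  density <- res$density
  mask <- res$mask

  with_seed(spec$seed, {
    # distractor bones: parallel tubes beside the target, clipped at the FOV
    if (spec$n_distractors > 0) {
      for (k in seq_len(spec$n_distractors)) {
        side <- if (k %% 2 == 1) 1 else -1
        off_vox <- side * (max(r_vox) * 1.6 + 4 + 3 * (k - 1))
        dres <- paint_tube(density, mask, axis$row + off_vox * 0.4,
                           axis$col + off_vox, r_vox * 0.7, target = FALSE)
        density <- dres$density
      }
    }
    # cortical erosions: spheres centred on the shell mid-surface carve
    # background-density notches through the shell
    if (spec$n_erosions > 0) {
      er_vox <- spec$erosion_radius_mm / vs
      z_range <- spec$annotated_range
      for (k in seq_len(spec$n_erosions)) {
        ze <- sample(seq(z_range[1], z_range[2] - 1), 1) + 1L
        theta <- runif(1, 0, 2 * pi)
        rr <- r_vox[ze] - shell_vox / 2
        ce_row <- axis$row[ze] + rr * cos(theta)
        ce_col <- axis$col[ze] + rr * sin(theta)
        zs <- max(1L, ze - ceiling(er_vox)):min(d[3], ze + ceiling(er_vox))
        for (z in zs) {
          dz2 <- (z - ze)^2
          dist2 <- outer((rows - ce_row)^2, (cols - ce_col)^2, `+`) + dz2
          hit <- dist2 <= er_vox^2
          if (any(hit)) {
            sl <- density[, , z]
            sl[hit] <- spec$background_density
            density[, , z] <- sl
          }
        }
      }
    }
    if (spec$noise_sigma > 0) {
      density <- density + array(rnorm(prod(d), 0, spec$noise_sigma), dim = d)
    }
  })

  if (spec$laterality == "left") {
    density <- density[, rev(seq_len(d[2])), , drop = FALSE]
    mask <- mask[, rev(seq_len(d[2])), , drop = FALSE]
  }

  cal <- calibration()
  vol <- calibrated_volume(
    intensities = invert_calibration(density, cal),
    voxel_size_mm = vs, calibration = cal,
    laterality = spec$laterality,
    case_id = sprintf("phantom_seed%d", spec$seed)
  )
  msk <- binary_mask(mask, voxel_size_mm = vs,
                     annotated_range = spec$annotated_range)
  list(volume = vol, mask = msk, spec = spec)
}

#' Generate a reproducible synthetic cohort
#'
#' Samples per-case phantom specifications around `base_spec`, generates each
#' phantom, and derives the expert-style contour annotation from the
#' ground-truth mask restricted to the annotated slice range. The laterality
#' mix defaults to the clinical left-hand proportion of 130/541.
#'
#' @param n Number of cases (>= 1).
#' @param base_spec A [phantom_spec()] providing defaults.
#' @param variation Named list of length-2 numeric ranges for any of
#'   `slices`, `bone_radius_mm`, `cortical_density`, `trabecular_density`,
#'   `noise_sigma`, `axis_curvature_mm`, `n_erosions`. A zero-width range
#'   pins the field to that value. An empty (length-0) range is a
#'   configuration error.
#' @param left_prob Probability that a case is a left hand (default 130/541).
#' @param seed Cohort seed; all per-case specs derive from it.
#' @return A list with `cases` (each a list with `volume`, `mask`,
#'   `annotation`, `spec`) and `metadata`, a tibble with one row per case
#'   (case_id, laterality, slices, densities, noise, erosions, seed).
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(), variation = list(),
                            left_prob = 130 / 541, seed = 1L) {
  if (n < 1) stop_mcv("n must be >= 1", "mcv_config_error")
  known <- c("slices", "bone_radius_mm", "cortical_density",
             "trabecular_density", "noise_sigma", "axis_curvature_mm",
             "n_erosions")
  for (nm in names(variation)) {
    if (!nm %in% known) {
      stop_mcv(sprintf("unknown variation field '%s'", nm), "mcv_config_error")
    }
    if (length(variation[[nm]]) != 2) {
      stop_mcv(sprintf("variation range for '%s' must have length 2", nm),
               "mcv_config_error")
    }
  }

  draw <- function(nm, default) {
    rg <- variation[[nm]]
    if (is.null(rg)) return(default)
    runif(1, min(rg), max(rg))
  }

  cases <- vector("list", n)
  meta <- vector("list", n)
  with_seed(derive_seed(seed, "cohort"), {
    for (i in seq_len(n)) {
      slices <- as.integer(round(draw("slices", base_spec$grid_shape[3])))
      lat <- if (runif(1) < left_prob) "left" else "right"
      spec_i <- phantom_spec(
        grid_shape = c(base_spec$grid_shape[1:2], slices),
        voxel_size_mm = base_spec$voxel_size_mm,
        cortical_density = draw("cortical_density", base_spec$cortical_density),
        trabecular_density = draw("trabecular_density", base_spec$trabecular_density),
        background_density = base_spec$background_density,
        shell_thickness_mm = base_spec$shell_thickness_mm,
        bone_radius_mm = draw("bone_radius_mm",
                              max(base_spec$radius_profile_mm)),
        axis_curvature_mm = draw("axis_curvature_mm", base_spec$axis_curvature_mm),
        n_erosions = as.integer(round(draw("n_erosions", base_spec$n_erosions))),
        erosion_radius_mm = base_spec$erosion_radius_mm,
        n_distractors = base_spec$n_distractors,
        noise_sigma = draw("noise_sigma", base_spec$noise_sigma),
        laterality = lat,
        annotated_range = c(0L, ceiling(0.8 * slices)),
        seed = derive_seed(seed, paste0("case", i))
      )
      ph <- generate_phantom(spec_i)
      ph$volume$case_id <- sprintf("case%03d", i)
      ann <- mask_to_contour(ph$mask, laterality = lat,
                             case_id = ph$volume$case_id)
      cases[[i]] <- list(volume = ph$volume, mask = ph$mask,
                         annotation = ann, spec = spec_i)
      meta[[i]] <- tibble::tibble(
        case_id = ph$volume$case_id,
        laterality = lat,
        slices = slices,
        cortical_density = spec_i$cortical_density,
        trabecular_density = spec_i$trabecular_density,
        noise_sigma = spec_i$noise_sigma,
        n_erosions = spec_i$n_erosions,
        annotated_start = spec_i$annotated_range[1],
        annotated_end = spec_i$annotated_range[2],
        seed = spec_i$seed
      )
    }
  })
  list(cases = cases, metadata = dplyr::bind_rows(meta))
}
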