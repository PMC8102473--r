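make_case <- function(slices = 20L, voi = c(4L, 16L)) {
  spec <- phantom_spec(grid_shape = c(32L, 32L, slices), bone_radius_mm = 0.8,
                       shell_thickness_mm = 0.2, axis_curvature_mm = 0.1,
                       noise_sigma = 0, n_distractors = 0L,
                       annotated_range = voi, seed = 2L)
  ph <- generate_phantom(spec)
  ann <- mask_to_contour(ph$mask)
  list(vol = ph$volume, ann = ann, mask = ph$mask)
}

test_that("extract_annotated_region drops exactly the un-annotated slices", {
  cs <- make_case(slices = 20L, voi = c(4L, 16L))
  st <- extract_annotated_region(cs$vol, cs$ann)
  expect_identical(dim(st$volume$intensities)[3], 12L)
  expect_identical(st$record$annotated_range, c(4L, 16L))
  expect_identical(st$record$original_shape, c(32L, 32L, 20L))
  expect_identical(st$volume$intensities, cs$vol$intensities[, , 5:16])
})

test_that("a VOI covering all slices leaves the volume unchanged", {
  cs <- make_case(slices = 10L, voi = c(0L, 10L))
  st <- extract_annotated_region(cs$vol, cs$ann)
  expect_identical(st$volume$intensities, cs$vol$intensities)
})

test_that("a VOI outside the volume is a range error", {
  cs <- make_case(slices = 20L, voi = c(4L, 16L))
  cs$ann$voi <- c(15L, 26L)
  expect_error(extract_annotated_region(cs$vol, cs$ann),
               class = "mcv_range_error")
})

test_that("resizing preserves constants and full masks", {
  vol <- calibrated_volume(array(7.5, c(20, 20, 10)))
  msk <- binary_mask(array(1, c(20, 20, 10)))
  rec <- mcvbmd:::new_preprocess_record(c(20, 20, 10), c(0, 10))
  out <- resize_case(vol, msk, rec, target_shape = c(16L, 16L, 8L))
  expect_true(all(abs(out$volume$intensities - 7.5) < 1e-12))
  expect_true(all(out$mask$values == 1))
  expect_equal(out$record$resize_factors, c(16, 16, 8) / c(20, 20, 10))
})

test_that("downscaling a disk mask approximately preserves its area", {
  sl <- matrix(0, 64, 64)
  for (r in 1:64) for (cc in 1:64) {
    if ((r - 32)^2 + (cc - 32)^2 <= 20^2) sl[r, cc] <- 1
  }
  msk <- binary_mask(array(rep(sl, 8), c(64, 64, 8)))
  vol <- calibrated_volume(array(0, c(64, 64, 8)))
  rec <- mcvbmd:::new_preprocess_record(c(64, 64, 8), c(0, 8))
  out <- resize_case(vol, msk, rec, target_shape = c(32L, 32L, 8L))
  area_in <- sum(sl) / (64 * 64)
  area_out <- sum(out$mask$values[, , 1]) / (32 * 32)
  expect_lt(abs(area_out - area_in) / area_in, 0.05)
  expect_true(all(out$mask$values %in% c(0, 1)))
})

test_that("flip_if_left mirrors only left hands and is an involution", {
  cs <- make_case()
  rec <- mcvbmd:::new_preprocess_record(dim(cs$vol$intensities), c(4L, 16L))
  r1 <- flip_if_left(cs$vol, cs$mask, rec, laterality = "right")
  expect_false(r1$record$was_flipped)
  expect_identical(r1$volume$intensities, cs$vol$intensities)
  l1 <- flip_if_left(cs$vol, cs$mask, rec, laterality = "left")
  expect_true(l1$record$was_flipped)
  l2 <- flip_if_left(l1$volume, l1$mask, rec, laterality = "left")
  expect_identical(l2$volume$intensities, cs$vol$intensities)
  expect_identical(l2$mask$values, cs$mask$values)
  expect_error(flip_if_left(cs$vol, cs$mask, rec, laterality = "ambidextrous"),
               class = "mcv_metadata_error")
})

test_that("a left phantom flipped equals its right-hand twin", {
  sr <- tiny_spec(laterality = "right", seed = 14L)
  sl <- tiny_spec(laterality = "left", seed = 14L)
  r <- generate_phantom(sr)
  l <- generate_phantom(sl)
  rec <- mcvbmd:::new_preprocess_record(sr$grid_shape, sr$annotated_range)
  fl <- flip_if_left(l$volume, l$mask, rec, laterality = "left")
  expect_identical(fl$volume$intensities, r$volume$intensities)
  expect_identical(fl$mask$values, r$mask$values)
})

test_that("normalization has the documented closed forms", {
  # stats on {0, 2} data: mean 1, variance 1, maps {0,2} -> {-1,+1}
  v <- array(c(0, 2), c(2, 1, 1))
  st <- compute_norm_stats(list(v), provenance = "train")
  expect_equal(st$mean, 1)
  expect_equal(st$variance, 1)
  expect_equal(as.vector(normalize_volume(v, st)), c(-1, 1))
  # self-normalization: sample mean 0, variance 1
  set.seed(3)
  x <- array(rnorm(1000, 5, 3), c(10, 10, 10))
  stx <- compute_norm_stats(list(x), provenance = "train")
  z <- normalize_volume(x, stx)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(mean(z^2) - 1), 1e-6)
  # shifting by c shifts the output by c / sigma
  z2 <- normalize_volume(x + 4, stx)
  expect_equal(z2, z + 4 / sqrt(stx$variance), tolerance = 1e-12)
})

test_that("degenerate and leaking normalization stats are flagged", {
  expect_error(compute_norm_stats(list(array(3, c(2, 2, 2))),
                                  provenance = "train"),
               class = "mcv_degenerate_error")
  expect_error(compute_norm_stats(list(array(rnorm(8), c(2, 2, 2)))),
               class = "mcv_provenance_error")
  expect_warning(compute_norm_stats(list(array(rnorm(8), c(2, 2, 2))),
                                    provenance = "cohort"),
                 class = "mcv_leakage_warning")
})

test_that("the preprocess record suffices to restore the original grid shape", {
  cs <- make_case(slices = 20L, voi = c(2L, 18L))
  pc <- preprocess_case(cs$vol, cs$ann, target_shape = c(16L, 16L, 16L))
  pred <- pc$y$values # stand-in prediction at network shape
  restored <- restore_dropped_slices(restore_full_resolution(pred, pc$record),
                                     pc$record)
  expect_identical(dim(restored$values), dim(cs$vol$intensities))
})
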