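disk_slice <- function(n, r0, c0, rad) {
  sl <- matrix(0, n, n)
  for (r in 1:n) for (cc in 1:n) {
    if ((r - r0)^2 + (cc - c0)^2 <= rad^2) sl[r, cc] <- 1
  }
  sl
}

test_that("flip_back mirrors iff the case was flipped and undoes flip_if_left", {
  arr <- array(as.numeric(rbinom(4 * 6 * 2, 1, 0.5)), c(4, 6, 2))
  rec_no <- mcvbmd:::new_preprocess_record(c(4, 6, 2), c(0, 2), was_flipped = FALSE)
  rec_yes <- mcvbmd:::new_preprocess_record(c(4, 6, 2), c(0, 2), was_flipped = TRUE)
  expect_identical(flip_back(arr, rec_no), arr)
  expect_identical(flip_back(flip_back(arr, rec_yes), rec_yes), arr)
  vol <- calibrated_volume(array(rnorm(48), c(4, 6, 2)), laterality = "left")
  msk <- binary_mask(arr)
  st <- flip_if_left(vol, msk, rec_no, laterality = "left")
  expect_identical(flip_back(st$mask, st$record)$values, arr)
  bad <- rec_no
  bad$was_flipped <- NULL
  expect_error(flip_back(arr, bad), class = "mcv_metadata_error")
})

test_that("interior holes are filled, matching the BFS flood-fill oracle", {
  sl <- disk_slice(20, 10, 10, 7)
  sl[9:11, 9:11] <- 0 # 3x3 interior hole
  m <- array(sl, c(20, 20, 1))
  out <- fill_holes(m)
  oracle <- bf_fill_holes_slice(sl > 0)
  expect_identical(out[, , 1] > 0, oracle)
  expect_identical(out[, , 1], disk_slice(20, 10, 10, 7))
})

test_that("fill_holes is idempotent, monotone, and leaves solid masks unchanged", {
  solid <- array(disk_slice(24, 12, 12, 8), c(24, 24, 1))
  expect_identical(fill_holes(solid), solid)
  sl <- disk_slice(24, 12, 12, 8)
  sl[10:12, 11:13] <- 0
  holey <- array(sl, c(24, 24, 1))
  once <- fill_holes(holey)
  twice <- fill_holes(once)
  expect_identical(once, twice)
  expect_true(all(once >= holey)) # output is a superset of the input
})

test_that("border-connected erosion notches are not filled", {
  sl <- disk_slice(30, 15, 15, 10)
  sl[14:16, 1:15] <- 0 # open channel from the boundary into the centre
  m <- array(sl, c(30, 30, 1))
  out <- fill_holes(m, tol = 0)
  oracle <- bf_fill_holes_slice(sl > 0)
  expect_identical(out[, , 1] > 0, oracle)
  expect_equal(sum(out[15, 1:13, 1]), 0) # channel stays open
  # with smoothing, the outer boundary may move by at most tol
  out1 <- fill_holes(m, tol = 1)
  expect_true(all(out1 >= m))
})

test_that("hole topology is judged per slice, not in 3D", {
  sl_holey <- disk_slice(20, 10, 10, 7)
  sl_holey[9:11, 9:11] <- 0
  # the hole is open along z in 3D, but each slice must still be filled
  m <- array(rep(sl_holey, 3), c(20, 20, 3))
  out <- fill_holes(m, tol = 0)
  for (z in 1:3) expect_identical(out[, , z], disk_slice(20, 10, 10, 7))
})

test_that("restoring resolution and dropped slices reproduces shapes and content", {
  spec <- tiny_spec(seed = 6L)
  ph <- generate_phantom(spec)
  ann <- mask_to_contour(ph$mask)
  pc <- preprocess_case(ph$volume, ann, target_shape = c(32L, 32L, 16L))
  restored <- restore_full_resolution(pc$y, pc$record)
  expect_identical(dim(restored$values),
                   c(48L, 48L, 20L)) # original in-plane x annotated count
  full <- restore_dropped_slices(restored, pc$record)
  expect_identical(dim(full$values), spec$grid_shape)
  expect_equal(sum(full$values[, , 21:24]), 0) # dropped slices restored as zeros
  # round trip on the ground truth at native resolution:
  voi <- ann$voi
  cropped <- ph$mask$values[, , (voi[1] + 1):voi[2]]
  rec <- mcvbmd:::new_preprocess_record(spec$grid_shape, voi)
  rec$resize_factors <- c(1, 1, 1)
  back <- restore_dropped_slices(restore_full_resolution(cropped, rec), rec)
  expect_identical(back$values[, , (voi[1] + 1):voi[2]], cropped)
})

test_that("downscale-then-restore keeps a large disk nearly intact", {
  sl <- disk_slice(128, 64, 64, 45)
  m <- array(rep(sl, 8), c(128, 128, 8))
  rec <- mcvbmd:::new_preprocess_record(c(128L, 128L, 8L), c(0L, 8L))
  vol <- calibrated_volume(array(0, c(128, 128, 8)))
  small <- resize_case(vol, binary_mask(m), rec, c(64L, 64L, 8L))
  up <- restore_full_resolution(small$mask, small$record)
  expect_gte(dsc(up$values, m), 0.98)
})

test_that("a full mask stays full through restoration and ranges are validated", {
  rec <- mcvbmd:::new_preprocess_record(c(24L, 24L, 10L), c(2L, 8L))
  full <- restore_full_resolution(array(1, c(16, 16, 6)), rec)
  expect_true(all(full$values == 1))
  expect_identical(dim(full$values), c(24L, 24L, 6L))
  expect_error(restore_dropped_slices(array(1, c(24, 24, 4)), rec),
               class = "mcv_range_error")
  norec <- list(annotated_range = NULL, original_shape = NULL)
  expect_error(restore_full_resolution(array(1, c(16, 16, 6)), norec),
               class = "mcv_metadata_error")
})

test_that("the full chain restores the original grid shape for varied cases", {
  set.seed(19)
  for (k in 1:3) {
    slices <- sample(c(18L, 22L, 26L), 1)
    lat <- sample(c("left", "right"), 1)
    spec <- phantom_spec(grid_shape = c(48L, 48L, slices),
                         bone_radius_mm = 1.2, shell_thickness_mm = 0.3,
                         noise_sigma = 5, n_distractors = 0L,
                         laterality = lat,
                         annotated_range = c(0L, slices - 4L), seed = k)
    ph <- generate_phantom(spec)
    ann <- mask_to_contour(ph$mask, laterality = lat)
    pc <- preprocess_case(ph$volume, ann, target_shape = c(32L, 32L, 16L))
    prob <- array(runif(prod(dim(pc$x$intensities))), dim(pc$x$intensities))
    out <- postprocess_prediction(prob, pc$record)
    expect_identical(dim(out$values), spec$grid_shape)
  }
})
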