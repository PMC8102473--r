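test_that("uniform-density phantom has exactly the class density everywhere in the mask", {
  spec <- tiny_spec(cortical_density = 300.0001, trabecular_density = 300,
                    background_density = 30)
  # make shell and interior effectively one class
  spec$cortical_density <- 300
  spec$trabecular_density <- 300 - 1e-9
  ph <- generate_phantom(spec)
  dens <- volume_density(ph$volume)
  inside <- ph$mask$values == 1
  expect_true(all(abs(dens[inside] - 300) < 1e-6))
})

test_that("straight-cylinder mask voxel count matches the analytic volume", {
  ns <- 50L
  spec <- phantom_spec(
    grid_shape = c(64L, 64L, ns), voxel_size_mm = 0.082,
    bone_radius_mm = rep(20 * 0.082, ns), shell_thickness_mm = 0.3,
    axis_curvature_mm = 0, noise_sigma = 0, n_distractors = 0L,
    annotated_range = c(0L, ns)
  )
  ph <- generate_phantom(spec)
  expected <- pi * 20^2 * ns
  expect_lt(abs(sum(ph$mask$values) - expected) / expected, 0.02)
  # brute-force point-in-cylinder oracle per voxel centre
  centre <- (64 - 1) / 2
  count <- 0
  for (r in 0:63) for (cc in 0:63) {
    if ((r - centre)^2 + (cc - centre)^2 <= 20^2) count <- count + 1
  }
  expect_identical(sum(ph$mask$values), count * ns)
})

test_that("left phantom is the exact column mirror of its right twin", {
  sr <- tiny_spec(noise_sigma = 10, laterality = "right", seed = 9L)
  sl <- tiny_spec(noise_sigma = 10, laterality = "left", seed = 9L)
  r <- generate_phantom(sr)
  l <- generate_phantom(sl)
  mirror <- function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  expect_identical(l$volume$intensities, mirror(r$volume$intensities))
  expect_identical(l$mask$values, mirror(r$mask$values))
})

test_that("identical seeds give bit-identical phantoms", {
  a <- generate_phantom(tiny_spec(noise_sigma = 20, n_erosions = 2L, seed = 4L))
  b <- generate_phantom(tiny_spec(noise_sigma = 20, n_erosions = 2L, seed = 4L))
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$mask$values, b$mask$values)
})

test_that("noise-free mask mean density equals the brute-force class mixture", {
  spec <- tiny_spec()
  ph <- generate_phantom(spec)
  dens <- volume_density(ph$volume)
  d <- spec$grid_shape
  # independent voxel-class tally from the geometry definition
  axis <- mcvbmd:::phantom_axis(spec)
  r_vox <- spec$radius_profile_mm / spec$voxel_size_mm
  shell_vox <- spec$shell_thickness_mm / spec$voxel_size_mm
  n_cort <- 0; n_trab <- 0
  for (z in seq_len(d[3])) {
    for (r in 0:(d[1] - 1)) for (cc in 0:(d[2] - 1)) {
      dist <- sqrt((r - axis$row[z])^2 + (cc - axis$col[z])^2)
      if (dist <= r_vox[z]) {
        if (dist <= r_vox[z] - shell_vox) n_trab <- n_trab + 1 else n_cort <- n_cort + 1
      }
    }
  }
  expected <- (n_cort * spec$cortical_density + n_trab * spec$trabecular_density) /
    (n_cort + n_trab)
  observed <- sum(dens * ph$mask$values) / sum(ph$mask$values)
  expect_equal(observed, expected, tolerance = 1e-12)
  expect_equal(n_cort + n_trab, sum(ph$mask$values))
})

test_that("erosions carve background density through the shell but stay in the mask", {
  s0 <- tiny_spec(seed = 31L)
  s1 <- tiny_spec(n_erosions = 3L, erosion_radius_mm = 0.4, seed = 31L)
  p0 <- generate_phantom(s0)
  p1 <- generate_phantom(s1)
  expect_identical(p0$mask$values, p1$mask$values)
  carved <- sum(p0$volume$intensities != p1$volume$intensities)
  expect_gt(carved, 0)
  d0 <- volume_density(p0$volume); d1 <- volume_density(p1$volume)
  expect_true(all(abs(d1[d1 != d0] - s1$background_density) < 1e-9))
})

test_that("geometry that does not fit the field of view is a geometry error", {
  expect_error(
    generate_phantom(phantom_spec(grid_shape = c(32L, 32L, 8L),
                                  bone_radius_mm = 2.0,
                                  shell_thickness_mm = 0.3,
                                  annotated_range = c(0L, 8L))),
    class = "mcv_geometry_error"
  )
})

test_that("phantom_spec validates its invariants", {
  expect_error(tiny_spec(cortical_density = 100, trabecular_density = 200),
               class = "mcv_config_error")
  expect_error(tiny_spec(shell_thickness_mm = 5), class = "mcv_config_error")
  expect_error(tiny_spec(annotated_range = c(10L, 100L)), class = "mcv_range_error")
})

test_that("degenerate cohort variation reproduces the base phantom", {
  base <- tiny_spec()
  coh <- generate_cohort(1, base,
                         variation = list(bone_radius_mm = c(1.2, 1.2)),
                         left_prob = 0, seed = 5)
  single <- generate_phantom(coh$cases[[1]]$spec)
  expect_identical(coh$cases[[1]]$mask$values, single$mask$values)
  expect_identical(dim(coh$cases[[1]]$volume$intensities), base$grid_shape)
})

test_that("cohort generation is deterministic and laterality follows the left proportion", {
  base <- tiny_spec(noise_sigma = 5)
  a <- generate_cohort(6, base, seed = 21)
  b <- generate_cohort(6, base, seed = 21)
  expect_identical(a$metadata, b$metadata)
  # binomial sampling of laterality across many seeds
  p_left <- 130 / 541
  n_each <- 8
  lefts <- vapply(1:25, function(s) {
    sum(generate_cohort(n_each, tiny_spec(grid_shape = c(24L, 24L, 4L),
                                          bone_radius_mm = 0.6,
                                          shell_thickness_mm = 0.15,
                                          axis_curvature_mm = 0,
                                          annotated_range = c(0L, 4L)),
                        seed = s)$metadata$laterality == "left")
  }, numeric(1))
  n_tot <- 25 * n_each
  expect_lt(abs(mean(lefts) / n_each - p_left),
            4 * sqrt(p_left * (1 - p_left) / n_tot))
})

test_that("empty variation ranges are a configuration error", {
  expect_error(generate_cohort(2, tiny_spec(),
                               variation = list(bone_radius_mm = numeric(0))),
               class = "mcv_config_error")
  expect_error(generate_cohort(2, tiny_spec(),
                               variation = list(nonsense = c(1, 2))),
               class = "mcv_config_error")
})
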