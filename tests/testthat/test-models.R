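test_that("full-width parameter shapes match the printed channel sequences", {
  set.seed(1)
  m <- build_unet2d(model_config_2d())
  ec <- c(3L, 64L, 64L, 128L, 256L, 512L)
  for (s in 1:5) {
    w1 <- m$params[[sprintf("enc%d.conv1.w", s)]]
    expect_identical(dim(w1), c(3L, 3L, ec[s], ec[s + 1]))
    w2 <- m$params[[sprintf("enc%d.conv2.w", s)]]
    expect_identical(dim(w2), c(3L, 3L, ec[s + 1], ec[s + 1]))
  }
  dc <- c(256L, 128L, 64L, 32L, 16L)
  for (t in 1:5) {
    w <- m$params[[sprintf("dec%d.conv1.w", t)]]
    expect_identical(dim(w)[4], dc[t])
  }
  expect_identical(dim(m$params$head.w), c(1L, 1L, 16L, 1L))
})

test_that("the 3D stage widths start at two and double per stage", {
  cfg <- model_config_3d()
  expect_identical(cfg$encoder_channels, c(2L, 4L, 8L, 16L, 32L))
  m <- build_unet3d(cfg)
  for (s in 1:5) {
    w <- m$params[[sprintf("enc%d.conv1.w", s)]]
    expect_identical(dim(w)[5], cfg$encoder_channels[s])
  }
})

test_that("the 2D forward pass maps a slice to a probability map of the same shape", {
  set.seed(2)
  m <- build_unet2d(model_config_2d(width_multiplier = 1 / 16))
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  p <- mcvbmd:::unet2d_forward(m, x)
  expect_identical(dim(p), c(64L, 64L, 1L, 1L))
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
  # constant input stays finite and in range too
  pc <- mcvbmd:::unet2d_forward(m, array(1, c(32, 32, 1, 1)))
  expect_true(all(pc >= 0 & pc <= 1))
})

test_that("spatial dims not divisible by 2^4 are a shape error", {
  set.seed(2)
  m <- build_unet2d(model_config_2d(width_multiplier = 1 / 16))
  expect_error(mcvbmd:::unet2d_forward(m, array(0, c(100, 100, 1, 1))),
               class = "mcv_shape_error")
  m3 <- build_unet3d(model_config_3d())
  expect_error(mcvbmd:::unet3d_forward(m3, array(0, c(16, 16, 20))),
               class = "mcv_shape_error")
})

test_that("the 3D forward pass keeps the spatial shape and its dropout is train-only", {
  set.seed(5)
  m <- build_unet3d(model_config_3d())
  x <- array(rnorm(16^3), c(16, 16, 16))
  p1 <- mcvbmd:::unet3d_forward(m, x, train = FALSE)
  p2 <- mcvbmd:::unet3d_forward(m, x, train = FALSE)
  expect_identical(dim(p1)[1:3], c(16L, 16L, 16L))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, p2) # eval mode is deterministic
  set.seed(11)
  t1 <- mcvbmd:::unet3d_forward(m, x, train = TRUE)
  set.seed(12)
  t2 <- mcvbmd:::unet3d_forward(m, x, train = TRUE)
  expect_false(identical(t1, t2)) # dropout is active in training mode
})

test_that("fixed seeds reproduce initial parameters exactly", {
  a <- withr::with_seed(99, build_unet2d(model_config_2d(width_multiplier = 1 / 16)))
  b <- withr::with_seed(99, build_unet2d(model_config_2d(width_multiplier = 1 / 16)))
  expect_identical(a$params, b$params)
  expect_warning(build_unet2d(model_config_2d(width_multiplier = 1 / 16,
                                              pretrained = TRUE)),
                 class = "mcv_pretrained_fallback")
})

test_that("dice_loss matches its closed forms", {
  y <- array(rbinom(4000, 1, 0.4), c(20, 20, 10))
  expect_lt(dice_loss(y, y), 1e-6) # identity on a >=1000-voxel mask
  x <- array(0, c(20, 20, 10))
  x[1:10, , ] <- 1
  yd <- array(0, c(20, 20, 10))
  yd[11:20, , ] <- 1
  expect_gt(dice_loss(x, yd), 1 - 1e-3) # disjoint, equal size
  expect_equal(1 - dice_loss(x, yd, smooth = 0), 0, tolerance = 1e-12)
  # |X| = |Y|, overlap half of each -> DSC 0.5 -> loss 0.5
  x2 <- array(0, c(4, 4, 1)); x2[1:2, , 1] <- 1
  y2 <- array(0, c(4, 4, 1)); y2[2:3, , 1] <- 1
  expect_equal(dice_loss(x2, y2, smooth = 0), 0.5)
  expect_error(dice_loss(array(0.5, c(2, 2, 1)), array(0, c(2, 2, 2))),
               class = "mcv_shape_error")
  expect_error(dice_loss(array(1.5, c(2, 2, 1)), array(0, c(2, 2, 1))),
               class = "mcv_range_error")
})

test_that("dice_loss with zero smoothing is exactly 1 - dsc on binary grids", {
  set.seed(21)
  for (k in 1:20) {
    x <- array(rbinom(125, 1, runif(1, 0.2, 0.7)), c(5, 5, 5))
    y <- array(rbinom(125, 1, runif(1, 0.2, 0.7)), c(5, 5, 5))
    if (sum(x) + sum(y) == 0) next
    expect_equal(dice_loss(x, y, smooth = 0), 1 - dsc(x, y), tolerance = 1e-12)
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(7)
  m <- build_unet2d(model_config_2d(width_multiplier = 1 / 32))
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  fw <- mcvbmd:::unet2d_forward(m, x, cache = TRUE)
  p <- fw$tape$values[[fw$out_id]]
  pg <- mcvbmd:::tape_backward(fw$tape, fw$out_id,
                               mcvbmd:::dice_loss_grad(p, y))
  loss_at <- function(params) {
    m2 <- m
    m2$params <- params
    dice_loss(mcvbmd:::unet2d_forward(m2, x), y)
  }
  for (nm in c("enc1.conv1.w", "enc2.n1.g", "dec4.conv2.w", "head.b")) {
    i <- sample(length(m$params[[nm]]), 1)
    eps <- 1e-5
    pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    an <- pg[[nm]][i]
    expect_equal(an, fd, tolerance = 1e-4)
  }
})
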