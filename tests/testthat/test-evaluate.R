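test_that("overlap metrics match their textbook examples", {
  x <- array(0, c(4, 4, 1)); x[1:2, 1:4, 1] <- 1 # |X| = 8
  y <- array(0, c(4, 4, 1)); y[2:3, 1:4, 1] <- 1 # |Y| = 8, intersection 4
  expect_equal(dsc(x, y), 0.5)
  expect_equal(iou(x, y), 1 / 3)
  expect_equal(dsc(y, y), 1)
  expect_equal(iou(y, y), 1)
  disj <- array(0, c(4, 4, 1)); disj[4, , 1] <- 1
  expect_equal(dsc(x * 0 + (x == 99), x), 0) # empty vs non-empty
  expect_equal(dsc(array(0, c(2, 2, 1)), array(0, c(2, 2, 1))), 1)
  expect_equal(iou(array(0, c(2, 2, 1)), array(0, c(2, 2, 1))), 1)
  expect_equal(pixel_accuracy(x, x), 1)
  # TP=1, TN=2, FP=1 on a 2x2 grid -> 0.75
  p <- array(c(1, 1, 0, 0), c(2, 2, 1))
  t_ <- array(c(1, 0, 0, 0), c(2, 2, 1))
  expect_equal(pixel_accuracy(p, t_), 0.75)
  # all-background prediction against 1% foreground -> 0.99
  yy <- array(0, c(10, 10, 1)); yy[1, 1, 1] <- 1
  expect_equal(pixel_accuracy(yy * 0, yy), 0.99)
  expect_error(dsc(array(0, c(2, 2, 1)), array(0, c(2, 3, 1))),
               class = "mcv_shape_error")
})

test_that("overlap metrics agree with explicit-loop counting on random masks", {
  set.seed(31)
  for (k in 1:60) {
    d <- c(sample(2:5, 1), sample(2:5, 1), sample(1:3, 1))
    x <- array(rbinom(prod(d), 1, runif(1, 0.1, 0.9)), d)
    y <- array(rbinom(prod(d), 1, runif(1, 0.1, 0.9)), d)
    ct <- bf_overlap_counts(x, y)
    if (ct$tp + ct$fp + ct$fn > 0) {
      expect_equal(dsc(x, y), 2 * ct$tp / (2 * ct$tp + ct$fp + ct$fn))
      expect_equal(iou(x, y), ct$tp / (ct$tp + ct$fp + ct$fn))
    }
    expect_equal(pixel_accuracy(x, y), (ct$tp + ct$tn) / prod(d))
    # symmetry
    expect_equal(dsc(x, y), dsc(y, x))
    expect_equal(iou(x, y), iou(y, x))
    expect_equal(pixel_accuracy(x, y), pixel_accuracy(y, x))
    # Jaccard-Dice identity
    expect_equal(iou(x, y), dsc(x, y) / (2 - dsc(x, y)), tolerance = 1e-12)
  }
})

test_that("auroc equals brute-force pair enumeration, including ties", {
  # worked example: pos {0.9, 0.8}, neg {0.8, 0.1} -> 0.875
  s <- c(0.9, 0.8, 0.8, 0.1)
  y <- c(1, 1, 0, 0)
  expect_equal(auroc(s, y), 0.875)
  expect_equal(auroc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1) # perfect separation
  expect_equal(auroc(rep(0.3, 6), c(1, 0, 1, 0, 0, 1)), 0.5) # constant scores
  expect_error(auroc(runif(5), rep(1, 5)), class = "mcv_degenerate_error")
  set.seed(17)
  for (k in 1:50) {
    n <- sample(5:100, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE) # ties likely
    expect_equal(auroc(s, y), bf_auroc(s, y), tolerance = 1e-12)
  }
})

test_that("run summaries report mean and SD over repeat-level means", {
  metrics <- tibble::tibble(
    configuration = "2d",
    `repeat` = rep(1:3, each = 2),
    metric = "dice",
    value = c(0.933, 0.933, 0.937, 0.937, 0.943, 0.943)
  )
  s <- summarize_runs(metrics)
  expect_equal(s$mean, mean(c(0.933, 0.937, 0.943)), tolerance = 1e-12)
  expect_equal(s$sd, sd(c(0.933, 0.937, 0.943)), tolerance = 1e-12)
  expect_equal(round(s$mean, 4), 0.9377)
  expect_equal(round(s$sd, 3), 0.005)
  single <- summarize_runs(tibble::tibble(configuration = "pre",
                                          `repeat` = 1, metric = "dice",
                                          value = c(0.97, 0.98)))
  expect_true(is.na(single$sd)) # single run: mean only
  allsame <- summarize_runs(tibble::tibble(configuration = "c",
                                           `repeat` = 1:3, metric = "m",
                                           value = rep(0.9, 3)))
  expect_equal(allsame$sd, 0)
})

test_that("agreement statistics recover closed forms on constructed pairs", {
  a <- c(250, 280, 300, 320, 210, 265)
  perfect <- agreement_stats(a, a)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$spearman_rho, 1)
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$bland_altman_mean_diff, 0)
  expect_equal(perfect$bland_altman_loa_high - perfect$bland_altman_loa_low, 0)
  off <- agreement_stats(a, a + 10)
  expect_equal(off$pearson_r, 1)
  expect_equal(off$bland_altman_mean_diff, 10)
  expect_equal(off$bland_altman_loa_high - off$bland_altman_loa_low, 0)
  expect_lt(off$icc, 1) # absolute agreement penalizes the constant offset
  # ICC(2,1) from an independent mean-squares computation
  mat <- cbind(a, a + 10)
  fit <- stats::aov(v ~ subj + rater,
                    data = data.frame(v = c(mat),
                                      subj = factor(rep(1:6, 2)),
                                      rater = factor(rep(1:2, each = 6))))
  ms <- summary(fit)[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_ref <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 6)
  expect_equal(off$icc, icc_ref, tolerance = 1e-10)
  prop <- agreement_stats(c(1, 2, 3), c(2, 4, 6))
  expect_equal(prop$pearson_r, 1)
  expect_equal(prop$spearman_rho, 1)
  expect_equal(prop$bland_altman_mean_diff, 2) # mean(2x - x) over 1..3
  expect_error(agreement_stats(rep(1, 5), rnorm(5)),
               class = "mcv_degenerate_error")
  expect_error(agreement_stats(1:2, 1:2), class = "mcv_config_error")
  expect_error(agreement_stats(1:5, 1:4), class = "mcv_shape_error")
})

test_that("Bland-Altman limits cover about 95% of Gaussian differences", {
  set.seed(71)
  cover <- replicate(40, {
    m <- rnorm(200, 300, 40)
    a <- m + rnorm(200, -5, 8)
    rep_ <- agreement_stats(m, a)
    mean(rep_$differences >= rep_$bland_altman_loa_low &
           rep_$differences <= rep_$bland_altman_loa_high)
  })
  expect_lt(abs(mean(cover) - 0.95), 0.02)
})

test_that("agreement reports tidy, glance, and plot", {
  r <- agreement_stats(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.3))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_true("icc" %in% td$statistic)
  gl <- glance(r)
  expect_identical(nrow(gl), 1L)
  p <- ggplot2::autoplot(r)
  expect_s3_class(p, "ggplot")
})
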