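#' Segmentation overlap metrics
#'
#' Pairwise overlap between a prediction `X` and a reference `Y` on the
#' same grid. `dsc` is the Dice similarity coefficient
#' `2|X intersect Y| / (|X| + |Y|)`; `iou` is the Jaccard index
#' `|X intersect Y| / |X union Y|`; `pixel_accuracy` is `(TP + TN) / N`.
#' Conventions: two empty masks agree perfectly (`dsc = iou = 1`); an empty
#' mask against a non-empty one scores 0. The two overlap measures are
#' linked by the identity `iou = dsc / (2 - dsc)`.
#'
#' @param x,y Binary arrays or [binary_mask()] objects of the same shape.
#' @return Scalar in [0, 1].
#' @export
#' @examples
#' a <- array(c(1, 1, 0, 0), c(2, 2, 1))
#' b <- array(c(1, 0, 1, 0), c(2, 2, 1))
#' dsc(a, b)            # 0.5
#' iou(a, b)            # 1/3
#' pixel_accuracy(a, b) # 0.5
dsc <- function(x, y) {
  x <- mask_values(x)
  y <- mask_values(y)
  assert_same_shape(x, y, "masks")
  sx <- sum(x)
  sy <- sum(y)
  if (sx + sy == 0) return(1)
  2 * sum(x * y) / (sx + sy)
}

#' @rdname dsc
#' @export
iou <- function(x, y) {
  x <- mask_values(x)
  y <- mask_values(y)
  assert_same_shape(x, y, "masks")
  inter <- sum(x * y)
  uni <- sum(x) + sum(y) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' @rdname dsc
#' @export
pixel_accuracy <- function(x, y) {
  x <- mask_values(x)
  y <- mask_values(y)
  assert_same_shape(x, y, "masks")
  sum(x * y + (1 - x) * (1 - y)) / length(x)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen foreground voxel scores higher
#' than a randomly chosen background voxel, with half credit for ties
#' (the Mann-Whitney statistic); identical to the trapezoidal area under
#' the ROC curve. Computed from ranks, verified in the tests against a
#' brute-force enumeration of all positive/negative pairs.
#'
#' @param scores Numeric prediction scores (any shape).
#' @param y Binary reference of the same length.
#' @return Scalar in [0, 1].
#' @export
auroc <- function(scores, y) {
  y <- as.vector(mask_values(y))
  scores <- as.vector(scores)
  if (length(scores) != length(y)) {
    stop_mcv("scores and reference must have the same length", "mcv_shape_error")
  }
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) {
    stop_mcv("AUROC undefined: reference contains a single class",
             "mcv_degenerate_error")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Per-configuration summary across training repeats
#'
#' Collapses per-case metrics to one row per (configuration, metric):
#' repeat-level means first, then mean and SD over repeats. A configuration
#' trained once gets its mean with an `NA` SD (reported as mean only).
#'
#' @param metrics Tibble/data.frame with columns `configuration`, `repeat`,
#'   `metric`, `value` (one row per case and metric).
#' @return Tibble with `configuration`, `metric`, `mean`, `sd`, `n_repeats`.
#' @export
summarize_runs <- function(metrics) {
  metrics <- tibble::as_tibble(metrics)
  needed <- c("configuration", "repeat", "metric", "value")
  if (!all(needed %in% names(metrics))) {
    stop_mcv(sprintf("metrics must have columns: %s",
                     paste(needed, collapse = ", ")), "mcv_config_error")
  }
  metrics |>
    dplyr::group_by(.data$configuration, .data$`repeat`, .data$metric) |>
    dplyr::summarise(rep_mean = mean(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$configuration, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$rep_mean),
      sd = if (dplyr::n() > 1) stats::sd(.data$rep_mean) else NA_real_,
      n_repeats = dplyr::n(),
      .groups = "drop"
    )
}

# ICC(2,1): two-way random effects, absolute agreement, single measurement,
# from the mean squares of the subjects x raters table.
icc_21 <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  grand <- mean(mat)
  row_means <- rowMeans(mat)
  col_means <- colMeans(mat)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((mat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Agreement between manual and automatic measurements
#'
#' Paired-measurement comparison of the two pipelines: Pearson and Spearman
#' correlations with two-sided p-values, the intraclass correlation
#' coefficient (two-way random effects, absolute agreement, single
#' measurement, i.e. ICC(2,1)), and Bland-Altman statistics (mean
#' difference `automatic - manual` and limits of agreement
#' `mean +- 1.96 SD` of the differences).
#'
#' @param manual,automatic Equal-length numeric vectors of paired
#'   measurements (n >= 3), e.g. D100 in mg HA/cm^3.
#' @param icc_type ICC variant; only `"ICC2_1"` is implemented, the
#'   config-exposed slot documents the choice.
#' @return An `agreement_report`: list with `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`, `icc`, `bland_altman_mean_diff`,
#'   `bland_altman_loa_low`, `bland_altman_loa_high`, `n_pairs`,
#'   `differences`, `means`.
#' @export
#' @examples
#' a <- c(250, 280, 300, 320, 210)
#' agreement_stats(a, a + 5)$bland_altman_mean_diff  # 5
agreement_stats <- function(manual, automatic, icc_type = "ICC2_1") {
  if (length(manual) != length(automatic)) {
    stop_mcv("manual and automatic must be paired (equal length)",
             "mcv_shape_error")
  }
  n <- length(manual)
  if (n < 3) stop_mcv("need at least 3 pairs", "mcv_config_error")
  if (stats::var(manual) == 0 || stats::var(automatic) == 0) {
    stop_mcv("zero-variance measurements: correlation undefined",
             "mcv_degenerate_error")
  }
  if (!identical(icc_type, "ICC2_1")) {
    stop_mcv("only ICC(2,1) is implemented", "mcv_config_error")
  }
  pe <- stats::cor.test(manual, automatic, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(manual, automatic, method = "spearman")
  )
  diffs <- automatic - manual
  md <- mean(diffs)
  sdd <- stats::sd(diffs)
  structure(
    list(
      pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
      spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
      icc = icc_21(cbind(manual, automatic)),
      icc_type = icc_type,
      bland_altman_mean_diff = md,
      bland_altman_loa_low = md - 1.96 * sdd,
      bland_altman_loa_high = md + 1.96 * sdd,
      n_pairs = n,
      differences = diffs,
      means = (manual + automatic) / 2
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    paste0("<agreement_report> n = %d pairs\n",
           "  Pearson r %.4f (p %.3g), Spearman rho %.4f (p %.3g)\n",
           "  ICC(2,1) %.4f\n",
           "  Bland-Altman: mean diff %.3f, LoA [%.3f, %.3f]\n"),
    x$n_pairs, x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p,
    x$icc, x$bland_altman_mean_diff, x$bland_altman_loa_low,
    x$bland_altman_loa_high))
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  tibble::tibble(
    statistic = c("pearson_r", "spearman_rho", "icc",
                  "bland_altman_mean_diff", "bland_altman_loa_low",
                  "bland_altman_loa_high"),
    value = c(x$pearson_r, x$spearman_rho, x$icc,
              x$bland_altman_mean_diff, x$bland_altman_loa_low,
              x$bland_altman_loa_high),
    p.value = c(x$pearson_p, x$spearman_p, NA, NA, NA, NA)
  )
}

#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    pearson_r = x$pearson_r,
    spearman_rho = x$spearman_rho,
    icc = x$icc,
    bland_altman_mean_diff = x$bland_altman_mean_diff
  )
}

#' Bland-Altman plot of an agreement report
#'
#' Differences (automatic - manual) against pair means, with the mean
#' difference and the 95% limits of agreement.
#'
#' @param object An [agreement_stats()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, diff = object$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bland_altman_mean_diff,
                        linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$bland_altman_loa_low,
                                       object$bland_altman_loa_high),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Automatic - manual",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Overlay of reference and predicted contours on one slice
#'
#' The qualitative review view: the slice's calibrated densities in gray,
#' reference and prediction boundaries as colored tiles.
#'
#' @param volume A [calibrated_volume()].
#' @param reference,prediction Binary masks on the volume's grid.
#' @param slice 1-based slice index to show.
#' @return A ggplot object.
#' @export
plot_slice_overlay <- function(volume, reference, prediction, slice) {
  dens <- volume_density(volume)[, , slice]
  rm_ <- mask_values(reference)[, , slice]
  pm_ <- mask_values(prediction)[, , slice]
  edge <- function(m) {
    m <- m > 0
    dil <- rbind(FALSE, m[-nrow(m), ]) | rbind(m[-1, ], FALSE) |
      cbind(FALSE, m[, -ncol(m)]) | cbind(m[, -1], FALSE)
    m & !(m & dil & rbind(TRUE, m[-nrow(m), ]) & rbind(m[-1, ], TRUE) &
            cbind(TRUE, m[, -ncol(m)]) & cbind(m[, -1], TRUE))
  }
  grid <- expand.grid(row = seq_len(nrow(dens)), col = seq_len(ncol(dens)))
  grid$density <- as.vector(dens)
  grid$overlay <- ifelse(as.vector(edge(rm_)), "reference",
                         ifelse(as.vector(edge(pm_)), "prediction", NA))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "mg HA/cm^3") +
    ggplot2::geom_point(
      data = grid[!is.na(grid$overlay), ],
      ggplot2::aes(color = .data$overlay), size = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Slice %d overlay", slice)) +
    ggplot2::theme_minimal()
}
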