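#' End-to-end pipeline configuration
#'
#' One object drives the whole chain: simulate -> preprocess -> train (or
#' load a checkpoint) -> predict -> postprocess -> quantify -> evaluate.
#' Every stochastic component derives its stream deterministically from
#' `seed`, so a rerun with the same configuration and seed reproduces every
#' artifact bit for bit. The default sizes are a desk-scale demonstration
#' (a small cohort of small phantoms and a width-reduced 2D network), not
#' the clinical-scale settings.
#'
#' @param out_dir Output directory for artifacts.
#' @param n_cases Number of synthetic cases.
#' @param base_spec [phantom_spec()] the cohort varies around.
#' @param variation Per-field ranges for [generate_cohort()].
#' @param target_shape Network input shape (rows, cols, slices).
#' @param model_config [model_config_2d()] or [model_config_3d()].
#' @param train_cfg [train_config()].
#' @param do_train If `FALSE`, `checkpoint` must point to a saved model.
#' @param checkpoint Optional path to a model saved with [save_model()].
#' @param postprocess_tol Hole-filling boundary tolerance (voxels).
#' @param write_masks Write predicted masks as NIfTI files.
#' @param seed Global pipeline seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir = tempfile("mcvbmd_run_"),
                            n_cases = 8L,
                            base_spec = phantom_spec(
                              grid_shape = c(64L, 64L, 40L),
                              bone_radius_mm = 1.6,
                              shell_thickness_mm = 0.35,
                              axis_curvature_mm = 0.25,
                              noise_sigma = 15,
                              n_distractors = 1L,
                              annotated_range = c(0L, 32L)
                            ),
                            variation = list(
                              bone_radius_mm = c(1.3, 1.8),
                              trabecular_density = c(150, 260)
                            ),
                            target_shape = c(64L, 64L, 16L),
                            model_config = model_config_2d(width_multiplier = 1 / 8),
                            train_cfg = train_config(
                              "2d", learning_rate = 3e-2, epochs = 8L,
                              patience = 4L
                            ),
                            do_train = TRUE,
                            checkpoint = NULL,
                            postprocess_tol = 1,
                            write_masks = FALSE,
                            seed = 1L) {
  structure(
    list(out_dir = out_dir, n_cases = as.integer(n_cases),
         base_spec = base_spec, variation = variation,
         target_shape = as.integer(target_shape),
         model_config = model_config, train_cfg = train_cfg,
         do_train = do_train, checkpoint = checkpoint,
         postprocess_tol = postprocess_tol, write_masks = write_masks,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Save / load a trained model
#'
#' Serializes the parameters together with an architecture descriptor so a
#' checkpoint documents its own configuration.
#'
#' @param model A trained model.
#' @param path Destination `.rds` path; a JSON architecture descriptor is
#'   written alongside.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mcv_model"))
  check_writable(path)
  saveRDS(model, path)
  jsonlite::write_json(
    list(architecture = model$architecture,
         config = unclass(model$config),
         n_parameters = sum(vapply(model$params, length, numeric(1)))),
    sub("\\.rds$", ".json", path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop_mcv(sprintf("checkpoint '%s' does not exist", path), "mcv_io_error")
  }
  m <- readRDS(path)
  if (!inherits(m, "mcv_model")) {
    stop_mcv("file does not contain a segmentation model", "mcv_format_error")
  }
  m
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[mcvbmd:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full automatic vBMD measurement pipeline
#'
#' Executes the whole chain on a synthetic cohort and compares the manual
#' (ground-truth annotation) and automatic (network) vBMD measurements.
#' Artifacts written under `config$out_dir`: `cohort.csv`,
#' `metrics.csv`, one `vbmd_<case>.json` per case (manual and automatic
#' D100, areas, volume), `agreement.json`, `history.csv`, and the model
#' checkpoint. Every JSON artifact is stamped with the configuration hash
#' and the seed. Per-stage wall-clock times are logged for information
#' only.
#'
#' @param config A [pipeline_config()].
#' @return List with `cohort` (metadata tibble), `vbmd` (tibble of paired
#'   measurements), `metrics` (per-case segmentation metrics tibble),
#'   `agreement` ([agreement_stats()] report), `model`, `history`,
#'   `config_hash`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[3]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- substr(object_hash(unclass(config)[setdiff(names(unclass(config)),
                                                         "out_dir")]), 1, 12)
  stamp <- list(config_hash = cfg_hash, seed = config$seed)

  step_t <- function(stage, expr) {
    ts <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      stop_mcv(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               "mcv_pipeline_error")
    })
    pipeline_log(stage, "done in %.1f s", proc.time()[3] - ts)
    res
  }

  cohort <- step_t("simulate", generate_cohort(
    config$n_cases, config$base_spec, config$variation, seed = config$seed))
  write.csv(cohort$metadata, file.path(config$out_dir, "cohort.csv"),
            row.names = FALSE)

  prep <- step_t("preprocess", lapply(cohort$cases, function(cs) {
    pc <- preprocess_case(cs$volume, cs$annotation, config$target_shape)
    list(id = cs$volume$case_id, x = pc$x$intensities, y = pc$y$values,
         record = pc$record, case = cs)
  }))

  ids <- vapply(prep, function(p) p$id, character(1))
  split <- split_dataset(ids, config$train_cfg$split_fractions,
                         seed = config$seed,
                         remainder_policy = config$train_cfg$remainder_policy)

  if (config$do_train) {
    model0 <- with_seed(derive_seed(config$seed, "model"), {
      if (inherits(config$model_config, "model_config_2d")) {
        build_unet2d(config$model_config)
      } else {
        build_unet3d(config$model_config)
      }
    })
    fit <- step_t("train", train_model(model0, prep, split, config$train_cfg))
    model <- fit$model
    history <- fit$history
    write.csv(history, file.path(config$out_dir, "history.csv"),
              row.names = FALSE)
    save_model(model, file.path(config$out_dir, "model.rds"))
  } else {
    if (is.null(config$checkpoint)) {
      stop_mcv(paste0(
        "training is disabled (do_train = FALSE) and no checkpoint is set; ",
        "either set do_train = TRUE or point `checkpoint` at a model saved ",
        "with save_model()"), "mcv_config_error")
    }
    model <- load_model(config$checkpoint)
    history <- tibble::tibble()
  }
  stats <- model$norm_stats

  results <- step_t("predict+postprocess+quantify", lapply(prep, function(p) {
    xn <- (p$x - stats$mean) / sqrt(stats$variance)
    prob <- predict_volume(model, xn)
    pred_full <- postprocess_prediction(
      prob, p$record, tol = config$postprocess_tol,
      voxel_size_mm = p$case$volume$voxel_size_mm)
    ref_full <- contour_to_mask(p$case$annotation,
                                dim(p$case$volume$intensities),
                                p$case$volume$voxel_size_mm)
    man <- compute_vbmd(p$case$volume, ref_full, mask_provenance = "manual")
    aut <- compute_vbmd(p$case$volume, pred_full, mask_provenance = "automatic")
    met <- tibble::tibble(
      case_id = p$id,
      split = dplyr::case_when(
        p$id %in% split$train_ids ~ "train",
        p$id %in% split$val_ids ~ "val",
        p$id %in% split$test_ids ~ "test",
        TRUE ~ "leftover"
      ),
      dsc = dsc(pred_full, ref_full),
      iou = iou(pred_full, ref_full),
      pixel_accuracy = pixel_accuracy(pred_full, ref_full),
      auroc = auroc(prob, p$y)
    )
    jsonlite::write_json(
      c(stamp, list(
        case_id = p$id,
        manual = tidy(man)[, -1], automatic = tidy(aut)[, -1]
      )),
      file.path(config$out_dir, sprintf("vbmd_%s.json", p$id)),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    if (config$write_masks) {
      write_mask(pred_full,
                 file.path(config$out_dir, sprintf("pred_%s.nii.gz", p$id)))
    }
    list(metrics = met, manual = man, automatic = aut)
  }))

  metrics <- dplyr::bind_rows(lapply(results, function(r) r$metrics))
  write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
            row.names = FALSE)
  vbmd <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(case_id = r$manual$case_id,
                   manual_d100 = r$manual$d100_mean_density,
                   automatic_d100 = r$automatic$d100_mean_density,
                   manual_area = r$manual$mean_slice_area_mm2,
                   automatic_area = r$automatic$mean_slice_area_mm2)
  }))

  agreement <- step_t("agree", agreement_stats(vbmd$manual_d100,
                                               vbmd$automatic_d100))
  jsonlite::write_json(
    c(stamp, list(n_pairs = agreement$n_pairs,
                  pearson_r = agreement$pearson_r,
                  spearman_rho = agreement$spearman_rho,
                  icc = agreement$icc,
                  bland_altman_mean_diff = agreement$bland_altman_mean_diff,
                  bland_altman_loa_low = agreement$bland_altman_loa_low,
                  bland_altman_loa_high = agreement$bland_altman_loa_high)),
    file.path(config$out_dir, "agreement.json"),
    auto_unbox = TRUE, digits = NA
  )

  pipeline_log("run", "pipeline finished in %.1f s", proc.time()[3] - t0)
  list(cohort = cohort$metadata, vbmd = vbmd, metrics = metrics,
       agreement = agreement, model = model, history = history,
       config_hash = cfg_hash, out_dir = config$out_dir)
}
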