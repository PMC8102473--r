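#' Training configuration
#'
#' Defaults follow the study protocol: Adam with framework-default
#' hyperparameters; learning rate 1e-5 and batch size 4 for the 2D network,
#' 1e-4 and batch size 1 for the 3D network (whole volumes); split fractions
#' 0.70 / 0.20 / 0.10 with the remainder left unassigned. Epoch budget and
#' early stopping are package choices (maximum 100 epochs, patience 15 on
#' validation Dice). `n_repeats` re-runs training with perturbed seeds
#' (`seed + repeat - 1`); the reference protocol repeats non-pretrained
#' runs three times and summarizes them as mean (SD).
#'
#' @param architecture `"2d"` or `"3d"`.
#' @param learning_rate Adam step size (architecture-dependent default).
#' @param batch_size Slices per step (2D) or volumes per step (3D).
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience on validation Dice.
#' @param n_repeats Number of independent repeats.
#' @param split_fractions Train/val/test fractions.
#' @param remainder_policy `"unassigned"` or `"to_train"`.
#' @param seed Base seed for shuffling, initialization and repeats.
#' @return A `train_config` object.
#' @export
train_config <- function(architecture = c("2d", "3d"),
                         learning_rate = NULL,
                         batch_size = NULL,
                         epochs = 100L,
                         patience = 15L,
                         n_repeats = 1L,
                         split_fractions = c(0.70, 0.20, 0.10),
                         remainder_policy = c("unassigned", "to_train"),
                         seed = 1L) {
  architecture <- match.arg(architecture)
  learning_rate <- learning_rate %||% if (architecture == "2d") 1e-5 else 1e-4
  batch_size <- as.integer(batch_size %||% if (architecture == "2d") 4L else 1L)
  if (batch_size < 1) stop_mcv("batch_size must be >= 1", "mcv_config_error")
  structure(
    list(architecture = architecture, learning_rate = learning_rate,
         batch_size = batch_size, epochs = as.integer(epochs),
         patience = as.integer(patience), n_repeats = as.integer(n_repeats),
         split_fractions = split_fractions,
         remainder_policy = match.arg(remainder_policy),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Split a cohort into train / validation / test sets
#'
#' Shuffles the case ids with the given seed and assigns
#' `floor(fraction * N)` cases per split; what the floors leave over is
#' handled by the remainder policy. The default, `"unassigned"`, reproduces
#' the reference cohort arithmetic: 541 cases at fractions 0.70/0.20/0.10
#' give 378/108/54 with one case left aside.
#'
#' @param case_ids Character or integer vector of at least 3 ids.
#' @param fractions Non-negative fractions summing to at most 1.
#' @param seed Shuffling seed (deterministic given the seed).
#' @param remainder_policy `"unassigned"` (leftovers reported separately) or
#'   `"to_train"` (leftovers join the training set).
#' @return A `split_result` with `train_ids`, `val_ids`, `test_ids`,
#'   `leftover_ids` (pairwise disjoint, union = cohort).
#' @export
#' @examples
#' s <- split_dataset(seq_len(541), seed = 1)
#' lengths(list(s$train_ids, s$val_ids, s$test_ids))  # 378 108 54
split_dataset <- function(case_ids, fractions = c(0.70, 0.20, 0.10),
                          seed = 1L,
                          remainder_policy = c("unassigned", "to_train")) {
  remainder_policy <- match.arg(remainder_policy)
  n <- length(case_ids)
  if (n < 3) stop_mcv("need at least 3 cases to split", "mcv_config_error")
  if (any(fractions < 0) || sum(fractions) > 1 + 1e-9) {
    stop_mcv("fractions must be non-negative and sum to at most 1",
             "mcv_config_error")
  }
  counts <- floor(fractions * n)
  shuffled <- with_seed(derive_seed(seed, "split"), sample(case_ids))
  idx <- cumsum(c(0, counts))
  take <- function(k) {
    if (counts[k] == 0) return(case_ids[0])
    shuffled[(idx[k] + 1):idx[k + 1]]
  }
  train <- take(1)
  val <- take(2)
  test <- take(3)
  leftover <- if (idx[4] < n) shuffled[(idx[4] + 1):n] else case_ids[0]
  if (remainder_policy == "to_train") {
    train <- c(train, leftover)
    leftover <- case_ids[0]
  }
  structure(
    list(train_ids = train, val_ids = val, test_ids = test,
         leftover_ids = leftover, fractions = fractions, seed = seed,
         remainder_policy = remainder_policy),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> train %d / val %d / test %d (leftover %d)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              length(x$leftover_ids)))
  invisible(x)
}

# gather preprocessed arrays for a set of ids
cases_by_id <- function(cases, ids) {
  all_ids <- vapply(cases, function(cs) cs$id, character(1))
  lapply(ids, function(i) cases[[match(i, all_ids)]])
}

#' Train a segmentation network
#'
#' Minimizes the soft Dice loss with Adam. Training samples are individual
#' slices for the 2D network and whole volumes for the 3D network.
#' Normalization statistics are computed inside this function from the
#' training split only and stored with the returned model, so no
#' information from validation or test cases can leak into them. Each
#' repeat perturbs the seed by its index; the checkpoint with the best
#' validation Dice is returned.
#'
#' @param model A built [build_unet2d()] / [build_unet3d()] model (its
#'   parameters seed repeat 1; later repeats re-initialize).
#' @param cases List of preprocessed cases, each
#'   `list(id, x = <3D intensity array>, y = <3D binary array>)` at the
#'   network input shape (unnormalized).
#' @param split A [split_dataset()] result over the case ids.
#' @param config A [train_config()].
#' @return List with `model` (best checkpoint, carrying `$norm_stats`),
#'   `history` (tibble: repeat, epoch, train_loss, val_loss, val_dice) and
#'   `best` (tibble row of the selected checkpoint).
#' @export
train_model <- function(model, cases, split, config) {
  stopifnot(inherits(model, "mcv_model"), inherits(split, "split_result"),
            inherits(config, "train_config"))
  if (length(split$train_ids) == 0 || length(split$val_ids) == 0) {
    stop_mcv("training requires non-empty train and validation splits",
             "mcv_config_error")
  }
  train_cases <- cases_by_id(cases, split$train_ids)
  val_cases <- cases_by_id(cases, split$val_ids)
  stats <- compute_norm_stats(lapply(train_cases, function(cs) cs$x),
                              provenance = "train")
  norm <- function(cs) {
    cs$x <- (cs$x - stats$mean) / sqrt(stats$variance)
    cs
  }
  train_cases <- lapply(train_cases, norm)
  val_cases <- lapply(val_cases, norm)

  is2d <- model$architecture == "2d"
  history <- list()
  best_overall <- NULL

  for (rep_i in seq_len(config$n_repeats)) {
    seed_i <- config$seed + rep_i - 1L
    model_i <- with_seed(derive_seed(seed_i, "init"), {
      if (rep_i == 1) model else if (is2d) build_unet2d(model$config) else
        build_unet3d(model$config)
    })
    params <- model_i$params
    astate <- adam_init(params)
    best <- list(dice = -Inf)
    wait <- 0L

    if (is2d) {
      # slice pool: (case index, slice index)
      pool <- do.call(rbind, lapply(seq_along(train_cases), function(i) {
        cbind(i, seq_len(dim(train_cases[[i]]$x)[3]))
      }))
    }

    for (epoch in seq_len(config$epochs)) {
      epoch_losses <- c()
      with_seed(derive_seed(seed_i, paste0("epoch", epoch)), {
        if (is2d) {
          ord <- sample(nrow(pool))
          batches <- base::split(ord, ceiling(seq_along(ord) / config$batch_size))
          for (bt in batches) {
            sel <- pool[bt, , drop = FALSE]
            H <- dim(train_cases[[1]]$x)[1]
            W <- dim(train_cases[[1]]$x)[2]
            xb <- array(0, c(H, W, 1, nrow(sel)))
            yb <- array(0, c(H, W, 1, nrow(sel)))
            for (j in seq_len(nrow(sel))) {
              xb[, , 1, j] <- train_cases[[sel[j, 1]]]$x[, , sel[j, 2]]
              yb[, , 1, j] <- train_cases[[sel[j, 1]]]$y[, , sel[j, 2]]
            }
            fw <- unet2d_forward(list(architecture = "2d",
                                      config = model_i$config,
                                      params = params), xb, cache = TRUE)
            pred <- fw$tape$values[[fw$out_id]]
            loss <- dice_loss(pred, yb)
            if (!is.finite(loss)) {
              stop_mcv(sprintf(
                "non-finite loss at repeat %d epoch %d; aborting", rep_i, epoch),
                "mcv_training_error")
            }
            g <- dice_loss_grad(pred, yb)
            pg <- tape_backward(fw$tape, fw$out_id, g)
            upd <- adam_step(params, pg, astate, config$learning_rate)
            params <- upd$params
            astate <- upd$state
            epoch_losses <- c(epoch_losses, loss)
          }
        } else {
          ord <- sample(length(train_cases))
          for (i in ord) {
            cs <- train_cases[[i]]
            fw <- unet3d_forward(list(architecture = "3d",
                                      config = model_i$config,
                                      params = params), cs$x,
                                 train = TRUE, cache = TRUE)
            pred <- fw$tape$values[[fw$out_id]]
            y <- cs$y
            dim(y) <- dim(pred)
            loss <- dice_loss(pred, y)
            if (!is.finite(loss)) {
              stop_mcv(sprintf(
                "non-finite loss at repeat %d epoch %d; aborting", rep_i, epoch),
                "mcv_training_error")
            }
            g <- dice_loss_grad(pred, y)
            pg <- tape_backward(fw$tape, fw$out_id, g)
            upd <- adam_step(params, pg, astate, config$learning_rate)
            params <- upd$params
            astate <- upd$state
            epoch_losses <- c(epoch_losses, loss)
          }
        }
      })
      model_now <- model_i
      model_now$params <- params
      val <- vapply(val_cases, function(cs) {
        p <- predict_volume(model_now, cs$x)
        c(dice_loss(p, cs$y), dsc(binarize(p), cs$y))
      }, numeric(2))
      val_loss <- mean(val[1, ])
      val_dice <- mean(val[2, ])
      history[[length(history) + 1L]] <- tibble::tibble(
        `repeat` = rep_i, epoch = epoch,
        train_loss = mean(epoch_losses),
        val_loss = val_loss, val_dice = val_dice
      )
      if (val_dice > best$dice) {
        best <- list(dice = val_dice, params = params, epoch = epoch,
                     rep_i = rep_i)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    if (is.null(best_overall) || best$dice > best_overall$dice) {
      best_overall <- best
    }
  }

  out_model <- model
  out_model$params <- best_overall$params
  out_model$norm_stats <- stats
  list(
    model = out_model,
    history = dplyr::bind_rows(history),
    best = tibble::tibble(`repeat` = best_overall$rep_i,
                          epoch = best_overall$epoch,
                          val_dice = best_overall$dice)
  )
}

#' Predict the segmentation probability grid for one volume
#'
#' The 2D network iterates over the slices of the volume (implemented as a
#' batched forward pass, which is bitwise identical to per-slice passes
#' because no layer couples samples); the 3D network predicts the whole
#' volume in a single forward pass. Evaluation mode: dropout is inactive.
#'
#' @param model A trained model.
#' @param volume 3D array at the network input shape, already normalized.
#' @param chunk Slices per forward pass for the 2D path (memory knob).
#' @return 3D array of probabilities in [0, 1], same shape as the input.
#' @export
predict_volume <- function(model, volume, chunk = 8L) {
  volume <- volume_values(volume)
  d <- dim(volume)
  if (length(d) != 3) stop_mcv("expected a 3D volume", "mcv_shape_error")
  if (model$architecture == "2d") {
    out <- array(0, d)
    for (start in seq(1, d[3], by = chunk)) {
      zs <- start:min(start + chunk - 1, d[3])
      xb <- array(volume[, , zs], c(d[1], d[2], 1, length(zs)))
      pb <- unet2d_forward(model, xb)
      out[, , zs] <- pb[, , 1, ]
    }
    out
  } else {
    p <- unet3d_forward(model, volume, train = FALSE)
    array(p, d)
  }
}

#' Threshold a probability grid into a binary mask
#'
#' Strict rule: a voxel is foreground iff its probability is strictly
#' greater than the threshold, so voxels at exactly the threshold are
#' background.
#'
#' @param prob Probability array in [0, 1].
#' @param threshold Default 0.5.
#' @return Binary array of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (any(prob < 0 | prob > 1)) {
    stop_mcv("probabilities must lie in [0, 1]", "mcv_range_error")
  }
  out <- (prob > threshold) * 1
  dim(out) <- dim(prob)
  out
}
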