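#' 2D segmentation network configuration
#'
#' A U-Net with a five-stage residual encoder and a standard U-Net decoder.
#' The full-scale encoder carries (3, 64, 64, 128, 256, 512) channels
#' (3-channel input; the grayscale slice is replicated across the three
#' input channels, matching encoders designed for natural-image
#' pretraining), the decoder (256, 128, 64, 32, 16). Downsampling is 2x2
#' max-pooling between stages, so inputs must be divisible by 2^4 in both
#' spatial dimensions. `width_multiplier` scales every channel count for
#' desk-scale training; scaled-down configurations are first-class, not a
#' test shortcut.
#'
#' @param encoder_channels Six integers: input channels then the five stage
#'   widths.
#' @param decoder_channels Five integers.
#' @param width_multiplier Multiplies all widths except the input (minimum
#'   resulting width 2).
#' @param pretrained If `TRUE`, request natural-image pretrained encoder
#'   weights. No pretrained weight source is available offline, so this
#'   falls back to random initialization with a warning.
#' @return A `model_config_2d` object.
#' @export
model_config_2d <- function(encoder_channels = c(3L, 64L, 64L, 128L, 256L, 512L),
                            decoder_channels = c(256L, 128L, 64L, 32L, 16L),
                            width_multiplier = 1,
                            pretrained = FALSE) {
  if (length(encoder_channels) != 6 || length(decoder_channels) != 5) {
    stop_mcv("need 6 encoder and 5 decoder channel counts", "mcv_config_error")
  }
  scale <- function(ch) pmax(2L, as.integer(round(ch * width_multiplier)))
  structure(
    list(
      encoder_channels = c(encoder_channels[1], scale(encoder_channels[-1])),
      decoder_channels = scale(decoder_channels),
      activation = "relu",
      width_multiplier = width_multiplier,
      pretrained = pretrained
    ),
    class = "model_config_2d"
  )
}

#' 3D segmentation network configuration
#'
#' A shallow volumetric U-Net, depth five: the first stage carries
#' `first_stage_channels` channels (default 2) and the width doubles at each
#' subsequent stage (2, 4, 8, 16, 32). LeakyReLU activations throughout;
#' dropout (default 60%) in the first stage only. The decoder mirrors the
#' encoder widths. All three spatial dimensions must be divisible by 2^4.
#'
#' @param first_stage_channels Width of stage one (doubled per stage).
#' @param depth Number of stages (fixed architecture family; default 5).
#' @param leaky_slope Negative slope of LeakyReLU (default 0.01).
#' @param dropout_p First-stage dropout probability (default 0.6).
#' @return A `model_config_3d` object.
#' @export
model_config_3d <- function(first_stage_channels = 2L, depth = 5L,
                            leaky_slope = 0.01, dropout_p = 0.6) {
  structure(
    list(
      encoder_channels = as.integer(first_stage_channels * 2^(seq_len(depth) - 1)),
      depth = as.integer(depth),
      leaky_slope = leaky_slope,
      dropout_p = dropout_p,
      activation = "leaky_relu"
    ),
    class = "model_config_3d"
  )
}

#' Build the 2D segmentation network
#'
#' Allocates and initializes all parameters for the configuration. Each
#' encoder stage is a residual double-convolution block (3x3 kernels, 1x1
#' projection where the width changes); decoder stages upsample (nearest),
#' concatenate the skip connection and apply a double convolution; a final
#' 1x1 convolution with a sigmoid produces the per-pixel foreground
#' probability. Initialization draws from the current RNG stream, so fixing
#' the seed reproduces the parameters bit for bit.
#'
#' @param config A [model_config_2d()].
#' @return A `unet2d` model object (parameters plus architecture descriptor).
#' @export
build_unet2d <- function(config = model_config_2d()) {
  stopifnot(inherits(config, "model_config_2d"))
  if (isTRUE(config$pretrained)) {
    rlang::warn(paste0(
      "no pretrained encoder weights are available in this installation; ",
      "falling back to random initialization"
    ), class = "mcv_pretrained_fallback")
  }
  ec <- config$encoder_channels
  dc <- config$decoder_channels
  params <- list()
  add <- function(name, p) {
    params[[paste0(name, ".w")]] <<- p$w
    params[[paste0(name, ".b")]] <<- p$b
  }
  add_norm <- function(name, ch) {
    params[[paste0(name, ".g")]] <<- rep(1, ch)
    params[[paste0(name, ".b")]] <<- rep(0, ch)
  }
  # encoder stages: enc1 .. enc5 (conv-norm-relu, conv-norm, +skip, relu)
  for (s in 1:5) {
    cin <- ec[s]
    cout <- ec[s + 1]
    add(sprintf("enc%d.conv1", s), init_conv2(3, cin, cout))
    add_norm(sprintf("enc%d.n1", s), cout)
    add(sprintf("enc%d.conv2", s), init_conv2(3, cout, cout))
    add_norm(sprintf("enc%d.n2", s), cout)
    if (cin != cout) {
      add(sprintf("enc%d.proj", s), init_conv2(1, cin, cout))
      add_norm(sprintf("enc%d.np", s), cout)
    }
  }
  # decoder stages: dec1 .. dec4 (up + skip), dec5 (refinement)
  skip_ch <- ec[5:2] # skips for dec1..dec4
  cin_prev <- ec[6]
  for (t in 1:4) {
    cin <- cin_prev + skip_ch[t]
    add(sprintf("dec%d.conv1", t), init_conv2(3, cin, dc[t]))
    add_norm(sprintf("dec%d.n1", t), dc[t])
    add(sprintf("dec%d.conv2", t), init_conv2(3, dc[t], dc[t]))
    add_norm(sprintf("dec%d.n2", t), dc[t])
    cin_prev <- dc[t]
  }
  add("dec5.conv1", init_conv2(3, dc[4], dc[5]))
  add_norm("dec5.n1", dc[5])
  add("dec5.conv2", init_conv2(3, dc[5], dc[5]))
  add_norm("dec5.n2", dc[5])
  add("head", init_conv2(1, dc[5], 1))
  structure(
    list(architecture = "2d", config = config, params = params),
    class = c("unet2d", "mcv_model")
  )
}

#' Build the 3D segmentation network
#'
#' Plain double-convolution stages (3x3x3 kernels) with LeakyReLU, dropout
#' in the first stage, 2x2x2 max-pooling between stages, and a mirrored
#' decoder (nearest upsampling + skip concatenation). A 1x1x1 convolution
#' with sigmoid forms the head.
#'
#' @param config A [model_config_3d()].
#' @return A `unet3d` model object.
#' @export
build_unet3d <- function(config = model_config_3d()) {
  stopifnot(inherits(config, "model_config_3d"))
  ec <- config$encoder_channels
  depth <- config$depth
  params <- list()
  add <- function(name, p) {
    params[[paste0(name, ".w")]] <<- p$w
    params[[paste0(name, ".b")]] <<- p$b
  }
  add_norm <- function(name, ch) {
    params[[paste0(name, ".g")]] <<- rep(1, ch)
    params[[paste0(name, ".b")]] <<- rep(0, ch)
  }
  cin <- 1L
  for (s in seq_len(depth)) {
    add(sprintf("enc%d.conv1", s), init_conv3(3, cin, ec[s]))
    add_norm(sprintf("enc%d.n1", s), ec[s])
    add(sprintf("enc%d.conv2", s), init_conv3(3, ec[s], ec[s]))
    add_norm(sprintf("enc%d.n2", s), ec[s])
    cin <- ec[s]
  }
  cin_prev <- ec[depth]
  for (t in seq_len(depth - 1)) {
    skip <- ec[depth - t]
    cin <- cin_prev + skip
    add(sprintf("dec%d.conv1", t), init_conv3(3, cin, skip))
    add_norm(sprintf("dec%d.n1", t), skip)
    add(sprintf("dec%d.conv2", t), init_conv3(3, skip, skip))
    add_norm(sprintf("dec%d.n2", t), skip)
    cin_prev <- skip
  }
  add("head", init_conv3(1, ec[1], 1))
  structure(
    list(architecture = "3d", config = config, params = params),
    class = c("unet3d", "mcv_model")
  )
}

#' @export
print.mcv_model <- function(x, ...) {
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<%s> %s U-Net, %s parameters\n",
              class(x)[1], x$architecture, format(npar, big.mark = ",")))
  invisible(x)
}

check_div16 <- function(d, what) {
  if (any(d %% 16 != 0)) {
    stop_mcv(sprintf(
      "%s spatial dims (%s) must be divisible by 2^4 for the 5-stage encoder",
      what, paste(d, collapse = "x")), "mcv_shape_error")
  }
}

# Forward pass for the 2D net. `x`: (H, W, 1, N) or (H, W) slice.
# Returns list(tape, out_id) when cache = TRUE, else the output array.
unet2d_forward <- function(model, x, cache = FALSE) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L, 1L)
  d <- dim(x)
  check_div16(d[1:2], "input")
  cin <- model$config$encoder_channels[1]
  if (d[3] == 1 && cin > 1) {
    # replicate the grayscale slice across the encoder's input channels
    x <- x[, , rep(1L, cin), , drop = FALSE]
  }
  tape <- new_tape(model$params)
  xin <- t_input(tape, x)
  block <- function(xid, stage) {
    h <- t_conv2(tape, xid, sprintf("enc%d.conv1", stage))
    h <- t_relu(tape, t_inorm(tape, h, sprintf("enc%d.n1", stage)))
    h <- t_conv2(tape, h, sprintf("enc%d.conv2", stage))
    h <- t_inorm(tape, h, sprintf("enc%d.n2", stage))
    skip <- if (!is.null(model$params[[sprintf("enc%d.proj.w", stage)]])) {
      t_inorm(tape, t_conv2(tape, xid, sprintf("enc%d.proj", stage)),
              sprintf("enc%d.np", stage))
    } else {
      xid
    }
    t_relu(tape, t_add(tape, h, skip))
  }
  f1 <- block(xin, 1)
  f2 <- block(t_pool2(tape, f1), 2)
  f3 <- block(t_pool2(tape, f2), 3)
  f4 <- block(t_pool2(tape, f3), 4)
  f5 <- block(t_pool2(tape, f4), 5)
  dec <- function(xid, skipid, stage) {
    h <- t_concat(tape, t_up2(tape, xid), skipid)
    h <- t_conv2(tape, h, sprintf("dec%d.conv1", stage))
    h <- t_relu(tape, t_inorm(tape, h, sprintf("dec%d.n1", stage)))
    h <- t_conv2(tape, h, sprintf("dec%d.conv2", stage))
    t_relu(tape, t_inorm(tape, h, sprintf("dec%d.n2", stage)))
  }
  d1 <- dec(f5, f4, 1)
  d2 <- dec(d1, f3, 2)
  d3 <- dec(d2, f2, 3)
  d4 <- dec(d3, f1, 4)
  d5 <- t_conv2(tape, d4, "dec5.conv1")
  d5 <- t_relu(tape, t_inorm(tape, d5, "dec5.n1"))
  d5 <- t_conv2(tape, d5, "dec5.conv2")
  d5 <- t_relu(tape, t_inorm(tape, d5, "dec5.n2"))
  out <- t_sigmoid(tape, t_conv2(tape, d5, "head"))
  if (cache) list(tape = tape, out_id = out) else tape$values[[out]]
}

# Forward pass for the 3D net. `x`: (H, W, D) volume or (H, W, D, 1, 1).
unet3d_forward <- function(model, x, train = FALSE, cache = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L, 1L)
  d <- dim(x)
  check_div16(d[1:3], "input")
  cfg <- model$config
  tape <- new_tape(model$params)
  xin <- t_input(tape, x)
  depth <- cfg$depth
  block <- function(xid, stage) {
    h <- t_conv3(tape, xid, sprintf("enc%d.conv1", stage))
    h <- t_lrelu(tape, t_inorm(tape, h, sprintf("enc%d.n1", stage)),
                 cfg$leaky_slope)
    h <- t_conv3(tape, h, sprintf("enc%d.conv2", stage))
    h <- t_lrelu(tape, t_inorm(tape, h, sprintf("enc%d.n2", stage)),
                 cfg$leaky_slope)
    if (stage == 1) h <- t_dropout(tape, h, cfg$dropout_p, train)
    h
  }
  feats <- vector("integer", depth)
  h <- block(xin, 1)
  feats[1] <- h
  for (s in 2:depth) {
    h <- block(t_pool3(tape, h), s)
    feats[s] <- h
  }
  for (t in seq_len(depth - 1)) {
    h <- t_concat(tape, t_up3(tape, h), feats[depth - t])
    h <- t_conv3(tape, h, sprintf("dec%d.conv1", t))
    h <- t_lrelu(tape, t_inorm(tape, h, sprintf("dec%d.n1", t)),
                 cfg$leaky_slope)
    h <- t_conv3(tape, h, sprintf("dec%d.conv2", t))
    h <- t_lrelu(tape, t_inorm(tape, h, sprintf("dec%d.n2", t)),
                 cfg$leaky_slope)
  }
  out <- t_sigmoid(tape, t_conv3(tape, h, "head"))
  if (cache) list(tape = tape, out_id = out) else tape$values[[out]]
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * t) + s) / (sum(p) + sum(t) + s)` over the whole tensor,
#' with smoothing `s` (default 1) in numerator and denominator. On binary
#' inputs with `smooth = 0` this equals `1 - dsc(X, Y)` exactly;
#' with the default smoothing the difference is below 1e-6 for masks of
#' 1000+ voxels. Differentiable in the prediction, value in [0, 1].
#'
#' @param pred Probability grid in [0, 1].
#' @param target Binary grid of the same shape (or [binary_mask()]).
#' @param smooth Smoothing constant (default 1).
#' @return Scalar loss.
#' @export
#' @examples
#' dice_loss(array(1, c(4, 4, 4)), array(1, c(4, 4, 4)))  # ~0
dice_loss <- function(pred, target, smooth = 1) {
  target <- mask_values(target)
  assert_same_shape(pred, target, "pred and target")
  if (any(pred < 0 | pred > 1)) {
    stop_mcv("predictions must lie in [0, 1]", "mcv_range_error")
  }
  inter <- sum(pred * target)
  1 - (2 * inter + smooth) / (sum(pred) + sum(target) + smooth)
}

# Gradient of the soft Dice loss in the prediction.
dice_loss_grad <- function(pred, target, smooth = 1) {
  inter <- sum(pred * target)
  den <- sum(pred) + sum(target) + smooth
  num <- 2 * inter + smooth
  g <- -(2 * target * den - num) / den^2
  dim(g) <- dim(pred)
  g
}
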