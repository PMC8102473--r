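# Minimal reverse-mode tape for the segmentation networks.
#
# Tensors are plain R arrays: (H, W, C, N) for 2D nets, (H, W, D, C, N) for
# 3D nets. Convolutions run in compiled code (src/nn_ops.cpp); cheap
# elementwise ops stay in R. A forward pass records a tape of nodes; the
# backward pass walks it in reverse, accumulating gradients for every
# parameter name. No computation graph library exists in this environment,
# so this small engine is part of the package.

new_tape <- function(params) {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$values <- list()
  env$params <- params
  env
}

tape_push <- function(tape, op, inputs, value, extra = NULL) {
  id <- length(tape$nodes) + 1L
  tape$nodes[[id]] <- list(id = id, op = op, inputs = inputs, extra = extra)
  tape$values[[id]] <- value
  id
}

t_input <- function(tape, x) tape_push(tape, "input", integer(0), x)

t_conv2 <- function(tape, xid, pname) {
  force(xid)
  x <- tape$values[[xid]]
  w <- tape$params[[paste0(pname, ".w")]]
  b <- tape$params[[paste0(pname, ".b")]]
  out <- conv2d_fw(x, dim(x), w, dim(w), b)
  tape_push(tape, "conv2", xid, out, extra = list(pname = pname))
}

t_conv3 <- function(tape, xid, pname) {
  force(xid)
  x <- tape$values[[xid]]
  w <- tape$params[[paste0(pname, ".w")]]
  b <- tape$params[[paste0(pname, ".b")]]
  out <- conv3d_fw(x, dim(x), w, dim(w), b)
  tape_push(tape, "conv3", xid, out, extra = list(pname = pname))
}

t_relu <- function(tape, xid) {
  force(xid)
  x <- tape$values[[xid]]
  tape_push(tape, "relu", xid, pmax(x, 0))
}

t_lrelu <- function(tape, xid, slope = 0.01) {
  force(xid)
  x <- tape$values[[xid]]
  out <- ifelse(x > 0, x, slope * x)
  dim(out) <- dim(x)
  tape_push(tape, "lrelu", xid, out, extra = list(slope = slope))
}

t_sigmoid <- function(tape, xid) {
  force(xid)
  x <- tape$values[[xid]]
  tape_push(tape, "sigmoid", xid, 1 / (1 + exp(-x)))
}

t_add <- function(tape, aid, bid) {
  force(aid); force(bid)
  tape_push(tape, "add", c(aid, bid), tape$values[[aid]] + tape$values[[bid]])
}

t_dropout <- function(tape, xid, p, train) {
  force(xid)
  x <- tape$values[[xid]]
  if (!train || p <= 0) return(xid)
  keep <- array(stats::rbinom(length(x), 1, 1 - p), dim = dim(x)) / (1 - p)
  tape_push(tape, "dropout", xid, x * keep, extra = list(keep = keep))
}

# Instance normalization: per (channel, sample), standardize over the
# spatial dims, then scale/shift with learnable gamma/beta. The reference
# encoders normalize after every convolution; at batch sizes 4 and 1 the
# per-instance variant behaves like batch norm without running statistics,
# which keeps inference deterministic.
t_inorm <- function(tape, xid, pname, eps = 1e-5) {
  force(xid)
  x <- tape$values[[xid]]
  d <- dim(x)
  nsp <- prod(d[seq_len(length(d) - 2)])       # spatial size
  ncn <- prod(d[(length(d) - 1):length(d)])    # channels x samples
  xm <- matrix(x, nsp, ncn)
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  sdv <- sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, sdv, `/`)
  g <- tape$params[[paste0(pname, ".g")]]
  b <- tape$params[[paste0(pname, ".b")]]
  # gamma/beta are per-channel; replicate across samples
  nch <- d[length(d) - 1]
  nsm <- d[length(d)]
  gcol <- rep(g, times = nsm)
  bcol <- rep(b, times = nsm)
  out <- sweep(sweep(xhat, 2, gcol, `*`), 2, bcol, `+`)
  dim(out) <- d
  tape_push(tape, "inorm", xid, out,
            extra = list(pname = pname, xhat = xhat, sdv = sdv,
                         nsp = nsp, nch = nch, nsm = nsm))
}

# channel concat: channel axis is the second-to-last dim
t_concat <- function(tape, aid, bid) {
  force(aid); force(bid)
  a <- tape$values[[aid]]
  b <- tape$values[[bid]]
  da <- dim(a)
  db <- dim(b)
  nd <- length(da)
  caxis <- nd - 1L
  out <- array(0, dim = replace(da, caxis, da[caxis] + db[caxis]))
  ia <- lapply(seq_len(nd), function(i) seq_len(da[i]))
  ib <- lapply(seq_len(nd), function(i) seq_len(db[i]))
  io <- ia
  io[[caxis]] <- seq_len(da[caxis])
  out <- do.call(`[<-`, c(list(out), io, list(a)))
  io[[caxis]] <- da[caxis] + seq_len(db[caxis])
  out <- do.call(`[<-`, c(list(out), io, list(b)))
  tape_push(tape, "concat", c(aid, bid), out,
            extra = list(ca = da[caxis], cb = db[caxis]))
}

t_pool2 <- function(tape, xid) {
  force(xid)
  x <- tape$values[[xid]]
  r <- maxpool2_fw(x, dim(x))
  tape_push(tape, "pool2", xid, r$out,
            extra = list(argmax = r$argmax, xdim = dim(x)))
}

t_pool3 <- function(tape, xid) {
  force(xid)
  x <- tape$values[[xid]]
  r <- maxpool3_fw(x, dim(x))
  tape_push(tape, "pool3", xid, r$out,
            extra = list(argmax = r$argmax, xdim = dim(x)))
}

t_up2 <- function(tape, xid) {
  force(xid)
  x <- tape$values[[xid]]
  d <- dim(x)
  out <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
           drop = FALSE]
  tape_push(tape, "up2", xid, out)
}

t_up3 <- function(tape, xid) {
  force(xid)
  x <- tape$values[[xid]]
  d <- dim(x)
  out <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
           rep(seq_len(d[3]), each = 2), , , drop = FALSE]
  tape_push(tape, "up3", xid, out)
}

down2_sum <- function(g) {
  d <- dim(g)
  g <- g[seq(1, d[1], 2), , , , drop = FALSE] +
       g[seq(2, d[1], 2), , , , drop = FALSE]
  g[, seq(1, d[2], 2), , , drop = FALSE] +
    g[, seq(2, d[2], 2), , , drop = FALSE]
}

down3_sum <- function(g) {
  d <- dim(g)
  g <- g[seq(1, d[1], 2), , , , , drop = FALSE] +
       g[seq(2, d[1], 2), , , , , drop = FALSE]
  g <- g[, seq(1, d[2], 2), , , , drop = FALSE] +
       g[, seq(2, d[2], 2), , , , drop = FALSE]
  g[, , seq(1, d[3], 2), , , drop = FALSE] +
    g[, , seq(2, d[3], 2), , , drop = FALSE]
}

# Backward pass: `gout` is the gradient at node `out_id`. Returns a named
# list of parameter gradients.
tape_backward <- function(tape, out_id, gout) {
  grads <- vector("list", length(tape$nodes))
  pgrads <- list()
  grads[[out_id]] <- gout
  acc <- function(slot, g) {
    if (is.null(grads[[slot]])) grads[[slot]] <<- g else grads[[slot]] <<- grads[[slot]] + g
  }
  for (id in rev(seq_along(tape$nodes))) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    val <- tape$values[[id]]
    switch(node$op,
      input = NULL,
      conv2 = {
        xid <- node$inputs[1]
        x <- tape$values[[xid]]
        pn <- node$extra$pname
        w <- tape$params[[paste0(pn, ".w")]]
        bw <- conv2d_bw(x, dim(x), w, dim(w), g)
        acc(xid, bw$gx)
        wk <- paste0(pn, ".w"); bk <- paste0(pn, ".b")
        pgrads[[wk]] <- (pgrads[[wk]] %||% 0) + bw$gw
        pgrads[[bk]] <- (pgrads[[bk]] %||% 0) + bw$gb
      },
      conv3 = {
        xid <- node$inputs[1]
        x <- tape$values[[xid]]
        pn <- node$extra$pname
        w <- tape$params[[paste0(pn, ".w")]]
        bw <- conv3d_bw(x, dim(x), w, dim(w), g)
        acc(xid, bw$gx)
        wk <- paste0(pn, ".w"); bk <- paste0(pn, ".b")
        pgrads[[wk]] <- (pgrads[[wk]] %||% 0) + bw$gw
        pgrads[[bk]] <- (pgrads[[bk]] %||% 0) + bw$gb
      },
      relu = {
        x <- tape$values[[node$inputs[1]]]
        acc(node$inputs[1], g * (x > 0))
      },
      lrelu = {
        x <- tape$values[[node$inputs[1]]]
        s <- node$extra$slope
        acc(node$inputs[1], g * ifelse(x > 0, 1, s))
      },
      sigmoid = {
        acc(node$inputs[1], g * val * (1 - val))
      },
      add = {
        acc(node$inputs[1], g)
        acc(node$inputs[2], g)
      },
      dropout = {
        acc(node$inputs[1], g * node$extra$keep)
      },
      inorm = {
        ex <- node$extra
        gm <- matrix(g, ex$nsp, ex$nch * ex$nsm)
        gcol <- rep(tape$params[[paste0(ex$pname, ".g")]], times = ex$nsm)
        dxhat <- sweep(gm, 2, gcol, `*`)
        m1 <- colMeans(dxhat)
        m2 <- colMeans(dxhat * ex$xhat)
        dx <- sweep(sweep(dxhat, 2, m1) - sweep(ex$xhat, 2, m2, `*`),
                    2, ex$sdv, `/`)
        xdim <- dim(tape$values[[node$inputs[1]]])
        dim(dx) <- xdim
        acc(node$inputs[1], dx)
        dg_cs <- colSums(gm * ex$xhat)
        db_cs <- colSums(gm)
        dg <- rowSums(matrix(dg_cs, ex$nch, ex$nsm))
        db <- rowSums(matrix(db_cs, ex$nch, ex$nsm))
        gk <- paste0(ex$pname, ".g"); bk <- paste0(ex$pname, ".b")
        pgrads[[gk]] <- (pgrads[[gk]] %||% 0) + dg
        pgrads[[bk]] <- (pgrads[[bk]] %||% 0) + db
      },
      concat = {
        d <- dim(val)
        nd <- length(d)
        caxis <- nd - 1L
        ia <- lapply(seq_len(nd), function(i) seq_len(d[i]))
        ia[[caxis]] <- seq_len(node$extra$ca)
        ga <- do.call(`[`, c(list(g), ia, list(drop = FALSE)))
        ib <- lapply(seq_len(nd), function(i) seq_len(d[i]))
        ib[[caxis]] <- node$extra$ca + seq_len(node$extra$cb)
        gb <- do.call(`[`, c(list(g), ib, list(drop = FALSE)))
        acc(node$inputs[1], ga)
        acc(node$inputs[2], gb)
      },
      pool2 = {
        acc(node$inputs[1], maxpool2_bw(g, node$extra$argmax, node$extra$xdim))
      },
      pool3 = {
        acc(node$inputs[1], maxpool3_bw(g, node$extra$argmax, node$extra$xdim))
      },
      up2 = {
        acc(node$inputs[1], down2_sum(g))
      },
      up3 = {
        acc(node$inputs[1], down3_sum(g))
      },
      stop_mcv(sprintf("unknown op '%s' in backward pass", node$op),
               "mcv_internal_error")
    )
    grads[[id]] <- NULL # free
  }
  pgrads
}

# He-style initialization for a conv kernel.
init_conv2 <- function(k, cin, cout) {
  fan_in <- k * k * cin
  list(
    w = array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / fan_in)),
              dim = c(k, k, cin, cout)),
    b = numeric(cout)
  )
}

init_conv3 <- function(k, cin, cout) {
  fan_in <- k^3 * cin
  list(
    w = array(stats::rnorm(k^3 * cin * cout, 0, sqrt(2 / fan_in)),
              dim = c(k, k, k, cin, cout)),
    b = numeric(cout)
  )
}

# Adam with the framework-default hyperparameters
# (beta1 0.9, beta2 0.999, eps 1e-8).
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
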