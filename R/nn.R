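# Native CNN-LSTM engine: a time-distributed convolutional feature extractor
# (3x3 "same" convolutions + ReLU, batch normalization, max pooling) applied
# identically to every frame, whose flattened per-frame features feed an LSTM;
# the last hidden state passes through a fully connected layer to a 2-unit
# softmax. Trained with RMSprop on 2-class cross-entropy (the 2-unit softmax
# reading of binary cross-entropy). Forward, backward and the optimizer are
# implemented here; the conv/pool inner loops live in src/kernels.cpp.
#
# Batched activations are arrays of dim (H, W, C, N) with N = batch * frames,
# frame-major within each sample (n = (b-1)*T + t).

#' CNN-LSTM architecture specification
#'
#' Defaults are the published architecture: four time-distributed conv blocks
#' (3x3 kernels with 8/4, 16/8, 32/16 and 64 filters, each followed by batch
#' normalization and 2x2 max pooling with 1x1 stride), an LSTM with 100 units
#' (dropout 0.2, recurrent dropout 0.2, L2 regularizer 0.01 on its kernels), a
#' 100-unit fully connected layer, and a 2-unit softmax, trained with RMSprop
#' at learning rate 1e-4 for 20 epochs on inputs of shape
#' (frames, 101, 101, 3).
#'
#' @param frames Frames per video.
#' @param input_px Spatial side of each frame.
#' @param conv_blocks List of per-block filter-count vectors.
#' @param pool_size,pool_stride Max-pool geometry.
#' @param lstm_units,lstm_dropout,lstm_recurrent_dropout,lstm_l2 LSTM layer.
#' @param dense_units Fully connected layer width.
#' @param learning_rate,epochs RMSprop training protocol.
#' @return A `model_spec` list.
#' @export
model_spec <- function(frames = 20L, input_px = 101L,
                       conv_blocks = list(c(8L, 4L), c(16L, 8L),
                                          c(32L, 16L), c(64L)),
                       pool_size = 2L, pool_stride = 1L,
                       lstm_units = 100L, lstm_dropout = 0.2,
                       lstm_recurrent_dropout = 0.2, lstm_l2 = 0.01,
                       dense_units = 100L, learning_rate = 1e-4,
                       epochs = 20L) {
  stopifnot(all(unlist(conv_blocks) > 0), lstm_units > 0, dense_units > 0,
            pool_size >= 1, pool_stride >= 1, frames >= 1)
  structure(list(input_shape = c(frames = as.integer(frames),
                                 h = as.integer(input_px),
                                 w = as.integer(input_px), channels = 3L),
                 conv_blocks = lapply(conv_blocks, as.integer),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 lstm_units = as.integer(lstm_units),
                 lstm_dropout = lstm_dropout,
                 lstm_recurrent_dropout = lstm_recurrent_dropout,
                 lstm_l2 = lstm_l2,
                 dense_units = as.integer(dense_units),
                 output_units = 2L,
                 optimizer = "rmsprop",
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs)),
            class = "model_spec")
}

#' Reduced-width specification for desk-scale benchmarks
#'
#' Same layout as [model_spec()] but with halved filter counts, stride-2
#' pooling, a 50-unit LSTM and a shorter, faster training protocol, so that
#' the synthetic benchmarks run in minutes on one CPU. The full-width
#' published architecture remains available via [model_spec()].
#'
#' @inheritParams model_spec
#' @return A `model_spec` list.
#' @export
model_spec_small <- function(frames = 20L, epochs = 16L) {
  model_spec(frames = frames,
             conv_blocks = list(c(4L, 2L), c(8L, 4L), c(16L, 8L), c(32L)),
             pool_stride = 2L, lstm_units = 50L, dense_units = 50L,
             learning_rate = 3e-3, epochs = epochs)
}

# Architecture walk: spatial size after each block, flattened feature size.
spec_geometry <- function(spec) {
  h <- spec$input_shape[["h"]]
  for (b in seq_along(spec$conv_blocks)) {
    h <- (h - spec$pool_size) %/% spec$pool_stride + 1L
    if (h < 1) stop_cv("pooling shrinks frames below 1 px", "cognatevid_spec_error")
  }
  last_blk <- spec$conv_blocks[[length(spec$conv_blocks)]]
  cfinal <- last_blk[length(last_blk)]
  list(feat_h = h, feat_c = cfinal, flat = h * h * cfinal)
}

#' Closed-form per-layer parameter counts
#'
#' Trainable parameter counts for every layer of a [model_spec()], e.g. a 3x3
#' convolution over `Cin` channels with `Cout` filters has
#' `3*3*Cin*Cout + Cout` parameters (224 for block 1 conv 1 of the default
#' architecture).
#'
#' @param spec A [model_spec()].
#' @return Named integer vector of parameter counts.
#' @export
model_param_counts <- function(spec) {
  counts <- integer(0)
  cin <- spec$input_shape[["channels"]]
  for (b in seq_along(spec$conv_blocks)) {
    for (i in seq_along(spec$conv_blocks[[b]])) {
      cout <- spec$conv_blocks[[b]][i]
      counts[sprintf("block%d_conv%d", b, i)] <- 9L * cin * cout + cout
      cin <- cout
    }
    counts[sprintf("block%d_bn", b)] <- 2L * cin
  }
  g <- spec_geometry(spec)
  U <- spec$lstm_units
  counts["lstm"] <- 4L * U * (g$flat + U + 1L)
  counts["dense"] <- U * spec$dense_units + spec$dense_units
  counts["softmax"] <- spec$dense_units * spec$output_units + spec$output_units
  counts
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

#' Build an untrained CNN-LSTM model
#'
#' Allocates Glorot-uniform weights for every layer of the given
#' specification; the LSTM forget-gate bias is initialized to 1.
#'
#' @param spec A [model_spec()].
#' @param seed Initialization seed.
#' @return A `cnn_lstm` model object.
#' @export
build_model <- function(spec, seed = 1L) {
  arch <- list()
  params <- list()
  bn_state <- list()
  with_seed(seed, function() {
    cin <- spec$input_shape[["channels"]]
    li <- 0L
    for (b in seq_along(spec$conv_blocks)) {
      for (i in seq_along(spec$conv_blocks[[b]])) {
        li <- li + 1L
        cout <- spec$conv_blocks[[b]][i]
        nm <- sprintf("conv%d", li)
        params[[paste0(nm, ".W")]] <<- glorot_uniform(9 * cin, 9 * cout,
                                                      c(9 * cin, cout))
        params[[paste0(nm, ".b")]] <<- numeric(cout)
        arch[[length(arch) + 1L]] <<- list(type = "conv", name = nm,
                                           gradcam_name = sprintf("block%d_conv%d", b, i))
        cin <- cout
      }
      nm <- sprintf("bn%d", b)
      params[[paste0(nm, ".gamma")]] <<- rep(1, cin)
      params[[paste0(nm, ".beta")]] <<- numeric(cin)
      bn_state[[paste0(nm, ".mean")]] <<- numeric(cin)
      bn_state[[paste0(nm, ".var")]] <<- rep(1, cin)
      arch[[length(arch) + 1L]] <<- list(type = "bn", name = nm)
      arch[[length(arch) + 1L]] <<- list(type = "pool")
    }
    g <- spec_geometry(spec)
    U <- spec$lstm_units
    D <- g$flat
    params$lstm.Wx <<- glorot_uniform(D, U, c(D, 4 * U))
    params$lstm.Wh <<- glorot_uniform(U, U, c(U, 4 * U))
    b0 <- numeric(4 * U)
    b0[(U + 1):(2 * U)] <- 1          # forget-gate bias
    params$lstm.b <<- b0
    params$dense1.W <<- glorot_uniform(U, spec$dense_units,
                                       c(U, spec$dense_units))
    params$dense1.b <<- numeric(spec$dense_units)
    params$dense2.W <<- glorot_uniform(spec$dense_units, 2,
                                       c(spec$dense_units, 2))
    params$dense2.b <<- numeric(2)
  })
  structure(list(spec = spec, arch = arch, params = params,
                 bn_state = bn_state, bn_momentum = 0.9,
                 classes = c("non-cognate", "cognate"),
                 opt = list(), trained_epochs = 0L),
            class = "cnn_lstm")
}

#' @export
print.cnn_lstm <- function(x, ...) {
  n <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<cnn_lstm> %d conv layers, LSTM(%d), %s params, %d epochs trained\n",
              sum(vapply(x$arch, function(a) a$type == "conv", TRUE)),
              x$spec$lstm_units, format(n, big.mark = ","), x$trained_epochs))
  invisible(x)
}

BN_EPS <- 1e-5

# Feature-extractor forward. X: (H, W, C, N). Returns list(out, cache,
# bn_updates). In training mode batch statistics are used and running-stat
# updates are returned for the caller to fold into the model.
nn_feat_fwd <- function(model, X, train = FALSE, keep_cache = FALSE) {
  p <- model$params
  spec <- model$spec
  cache <- if (keep_cache) vector("list", length(model$arch)) else NULL
  bn_upd <- list()
  A <- X
  for (li in seq_along(model$arch)) {
    layer <- model$arch[[li]]
    if (layer$type == "conv") {
      Y <- .cpp_conv_fwd(A, dim(A), p[[paste0(layer$name, ".W")]],
                         p[[paste0(layer$name, ".b")]], 3L, TRUE)
      if (keep_cache) cache[[li]] <- list(x = A, y = Y)
      A <- Y
    } else if (layer$type == "bn") {
      nm <- layer$name
      g <- p[[paste0(nm, ".gamma")]]; be <- p[[paste0(nm, ".beta")]]
      rm_ <- model$bn_state[[paste0(nm, ".mean")]]
      rv_ <- model$bn_state[[paste0(nm, ".var")]]
      bf <- .cpp_bn_fwd(A, dim(A), g, be, rm_, rv_,
                        use_given = !train, eps = BN_EPS)
      m <- as.numeric(bf$mean); v <- as.numeric(bf$var)
      if (train) {
        bn_upd[[paste0(nm, ".mean")]] <- m
        bn_upd[[paste0(nm, ".var")]] <- v
      }
      if (keep_cache) cache[[li]] <- list(x = A, m = m, v = v, train = train)
      A <- bf$out
    } else {  # pool
      pr <- .cpp_maxpool_fwd(A, dim(A), spec$pool_size, spec$pool_stride)
      if (keep_cache) cache[[li]] <- list(idx = pr$idx, in_dims = dim(A))
      A <- pr$out
    }
  }
  list(out = A, cache = cache, bn_updates = bn_upd)
}

# Feature-extractor backward. dOut matches the forward output. Returns
# list(grads, conv_dA) where conv_dA[[gradcam_name]] is the gradient w.r.t.
# that conv layer's (post-ReLU) activation when `capture` names it.
nn_feat_bwd <- function(model, cache, dOut, capture = character(0)) {
  p <- model$params
  grads <- list()
  conv_dA <- list()
  dA <- dOut
  for (li in rev(seq_along(model$arch))) {
    layer <- model$arch[[li]]
    cc <- cache[[li]]
    if (layer$type == "pool") {
      dA <- .cpp_maxpool_bwd(dA, cc$idx, cc$in_dims)
    } else if (layer$type == "bn") {
      nm <- layer$name
      bb <- .cpp_bn_bwd(cc$x, dA, dim(cc$x), p[[paste0(nm, ".gamma")]],
                        cc$m, cc$v, train = isTRUE(cc$train), eps = BN_EPS)
      grads[[paste0(nm, ".gamma")]] <- as.numeric(bb$dgamma)
      grads[[paste0(nm, ".beta")]] <- as.numeric(bb$dbeta)
      dA <- bb$dx
    } else {  # conv (+ ReLU)
      nm <- layer$name
      if (layer$gradcam_name %in% capture) {
        conv_dA[[layer$gradcam_name]] <- dA
      }
      bw <- .cpp_conv_bwd(cc$x, dim(cc$x), p[[paste0(nm, ".W")]], dA, cc$y,
                          3L, need_dx = li > 1L || length(capture) > 0L)
      grads[[paste0(nm, ".W")]] <- bw$dW
      grads[[paste0(nm, ".b")]] <- as.numeric(bw$db)
      dA <- bw$dx
    }
  }
  list(grads = grads, conv_dA = conv_dA, dX = dA)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# LSTM + dense head forward. F: (D, B*T) frame-major per sample. Dropout
# masks (NULL = off) are (D, B) and (U, B), shared across time steps.
nn_head_fwd <- function(model, F, B, Tn, mask_x = NULL, mask_h = NULL,
                        keep_cache = FALSE) {
  p <- model$params
  U <- model$spec$lstm_units
  h <- matrix(0, U, B); cst <- matrix(0, U, B)
  steps <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    Xt <- F[, (seq_len(B) - 1) * Tn + t, drop = FALSE]
    xd <- if (is.null(mask_x)) Xt else Xt * mask_x
    hd <- if (is.null(mask_h)) h else h * mask_h
    Z <- crossprod(p$lstm.Wx, xd) + crossprod(p$lstm.Wh, hd) + p$lstm.b
    i <- sigmoid(Z[1:U, , drop = FALSE])
    f <- sigmoid(Z[(U + 1):(2 * U), , drop = FALSE])
    g <- tanh(Z[(2 * U + 1):(3 * U), , drop = FALSE])
    o <- sigmoid(Z[(3 * U + 1):(4 * U), , drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    if (keep_cache) {
      steps[[t]] <- list(xd = xd, hd = hd, i = i, f = f, g = g, o = o,
                         c_prev = c_prev, tc = tc)
    }
    h <- o * tc
  }
  A1z <- crossprod(p$dense1.W, h) + p$dense1.b
  A1 <- pmax(A1z, 0)
  logits <- crossprod(p$dense2.W, A1) + p$dense2.b
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  probs <- sweep(e, 2, colSums(e), "/")
  cache <- if (keep_cache) {
    list(steps = steps, h = h, A1 = A1, probs = probs, B = B, Tn = Tn,
         mask_x = mask_x, mask_h = mask_h)
  } else NULL
  list(probs = probs, logits = logits, cache = cache)
}

# Head backward from dLogits (2 x B). Returns grads and dF (D, B*T).
nn_head_bwd <- function(model, cache, dLogits) {
  p <- model$params
  U <- model$spec$lstm_units
  B <- cache$B; Tn <- cache$Tn
  grads <- list()
  grads$dense2.W <- cache$A1 %*% t(dLogits)
  grads$dense2.b <- rowSums(dLogits)
  dA1 <- p$dense2.W %*% dLogits
  dA1z <- dA1 * (cache$A1 > 0)
  grads$dense1.W <- cache$h %*% t(dA1z)
  grads$dense1.b <- rowSums(dA1z)
  dh_next <- p$dense1.W %*% dA1z
  dc_next <- matrix(0, U, B)
  dWx <- array(0, dim(p$lstm.Wx)); dWh <- array(0, dim(p$lstm.Wh))
  db <- numeric(4 * U)
  D <- nrow(p$lstm.Wx)
  dF <- matrix(0, D, B * Tn)
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    dh <- dh_next
    do_ <- dh * s$tc
    dc <- dc_next + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dc_next <- dc * s$f
    dZ <- rbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do_ * s$o * (1 - s$o))
    dWx <- dWx + s$xd %*% t(dZ)
    dWh <- dWh + s$hd %*% t(dZ)
    db <- db + rowSums(dZ)
    dx <- p$lstm.Wx %*% dZ
    if (!is.null(cache$mask_x)) dx <- dx * cache$mask_x
    dhp <- p$lstm.Wh %*% dZ
    if (!is.null(cache$mask_h)) dhp <- dhp * cache$mask_h
    dh_next <- dhp
    dF[, (seq_len(B) - 1) * Tn + t] <- dx
  }
  l2 <- model$spec$lstm_l2
  grads$lstm.Wx <- dWx + 2 * l2 * p$lstm.Wx
  grads$lstm.Wh <- dWh + 2 * l2 * p$lstm.Wh
  grads$lstm.b <- db
  list(grads = grads, dF = dF)
}

# Full forward + backward for one batch. X: (H, W, C, B*T); Y: one-hot (2, B).
# Returns loss (data term + L2), probs and grads.
nn_train_step_grads <- function(model, X, Y, B, Tn, dropout = TRUE) {
  spec <- model$spec
  ff <- nn_feat_fwd(model, X, train = TRUE, keep_cache = TRUE)
  Fm <- matrix(ff$out, ncol = B * Tn)
  mask_x <- mask_h <- NULL
  if (dropout && spec$lstm_dropout > 0) {
    keep <- 1 - spec$lstm_dropout
    mask_x <- matrix(rbinom(nrow(Fm) * B, 1, keep) / keep, nrow(Fm), B)
  }
  if (dropout && spec$lstm_recurrent_dropout > 0) {
    keep <- 1 - spec$lstm_recurrent_dropout
    mask_h <- matrix(rbinom(spec$lstm_units * B, 1, keep) / keep,
                     spec$lstm_units, B)
  }
  hf <- nn_head_fwd(model, Fm, B, Tn, mask_x, mask_h, keep_cache = TRUE)
  probs <- hf$probs
  eps <- 1e-12
  data_loss <- -mean(log(pmax(colSums(probs * Y), eps)))
  l2_loss <- spec$lstm_l2 * (sum(model$params$lstm.Wx^2) +
                             sum(model$params$lstm.Wh^2))
  dLogits <- (probs - Y) / B
  hb <- nn_head_bwd(model, hf$cache, dLogits)
  dOut <- hb$dF
  dim(dOut) <- dim(ff$out)
  fb <- nn_feat_bwd(model, ff$cache, dOut)
  list(loss = data_loss + l2_loss, data_loss = data_loss, probs = probs,
       grads = c(fb$grads, hb$grads), bn_updates = ff$bn_updates)
}

# RMSprop parameter update (rho = 0.9, eps = 1e-7), in the Keras convention.
# Gradients are clipped to a global norm of `clipnorm` first: occasional
# exploding gradients through the recurrent layer would otherwise wreck the
# learned features at scaled-up learning rates.
rmsprop_update <- function(model, grads, lr, clipnorm = 1.0) {
  rho <- 0.9; eps <- 1e-7
  if (is.finite(clipnorm)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
    if (gn > clipnorm) grads <- lapply(grads, function(g) g * (clipnorm / gn))
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    cache <- model$opt[[nm]]
    if (is.null(cache)) cache <- array(0, dim(as.array(g)))
    cache <- rho * cache + (1 - rho) * g^2
    model$opt[[nm]] <- cache
    upd <- model$params[[nm]] - lr * g / (sqrt(cache) + eps)
    dim(upd) <- dim(model$params[[nm]])   # keep plain vectors dimension-free
    model$params[[nm]] <- upd
  }
  model
}

fold_bn_updates <- function(model, bn_upd) {
  mom <- model$bn_momentum
  for (nm in names(bn_upd)) {
    model$bn_state[[nm]] <- mom * model$bn_state[[nm]] + (1 - mom) * bn_upd[[nm]]
  }
  model
}

# Assemble a batch input array (H, W, C, B*T) from a list of videos, each a
# (T, H, W, C) array (raw or numeric). Optional per-sample integer shifts:
# matrix (B, 2) of (dy, dx).
assemble_batch <- function(videos, shifts = NULL) {
  v1 <- videos[[1]]
  d <- dim(v1)
  Tn <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  B <- length(videos)
  X <- array(0, dim = c(H, W, C, B * Tn))
  for (b in seq_len(B)) {
    arr <- videos[[b]]
    if (is.raw(arr)) arr <- array(as.integer(arr), dim(arr))
    a <- aperm(arr, c(2, 3, 4, 1))       # (H, W, C, T)
    if (!is.null(shifts) && any(shifts[b, ] != 0)) {
      a <- shift_hwct(a, shifts[b, 1], shifts[b, 2])
    }
    X[, , , (b - 1) * Tn + seq_len(Tn)] <- a
  }
  X
}

# Shift an (H, W, C, T) array by (dy, dx) with zero fill.
shift_hwct <- function(a, dy, dx) {
  d <- dim(a)
  out <- array(0, d)
  H <- d[1]; W <- d[2]
  sr <- max(1, 1 + dy):min(H, H + dy)
  tr <- sr - dy
  sc <- max(1, 1 + dx):min(W, W + dx)
  tc <- sc - dx
  if (length(sr) && length(sc)) out[sr, sc, , ] <- a[tr, tc, , , drop = FALSE]
  out
}
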