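# Grad-CAM: gradient-weighted class activation maps localizing the image
# regions that drive the classification, computed at the first conv layer of
# the penultimate conv block.

bilinear_upsample <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == 1 && w == 1) return(matrix(m[1, 1], out_h, out_w))
  ri <- if (h == 1) rep(1, out_h) else (seq_len(out_h) - 1) * (h - 1) / (out_h - 1) + 1
  ci <- if (w == 1) rep(1, out_w) else (seq_len(out_w) - 1) * (w - 1) / (out_w - 1) + 1
  r0 <- pmin(floor(ri), h - 1); r1 <- r0 + 1; fr <- ri - r0
  c0 <- pmin(floor(ci), w - 1); c1 <- c0 + 1; fc <- ci - c0
  a <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
       m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
       m[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
       m[r1, c1, drop = FALSE] * outer(fr, fc)
  a
}

#' Grad-CAM localization maps for a video
#'
#' Backpropagates the classification score (pre-softmax logit) of the chosen
#' class to the first conv layer of the penultimate conv block, weights that
#' layer's per-frame activation channels by their spatially averaged
#' gradients, rectifies the weighted sum, normalizes over the whole video to
#' \[0, 1\] and bilinearly upsamples each frame to the input size.
#'
#' @param model A trained `cnn_lstm`.
#' @param video A [cell_video()] or binary `(T, H, W, 3)` array.
#' @param class Class whose score is explained (`"cognate"` or
#'   `"non-cognate"`).
#' @return A `gradcam_map`: array `(frames, H, W)` with values in \[0, 1\]
#'   (all zero when the rectified gradients vanish).
#' @export
grad_cam <- function(model, video, class = c("cognate", "non-cognate")) {
  class <- match.arg(class)
  arr <- video_arrays(list(video))[[1]]
  if (is.raw(arr)) arr <- array(as.integer(arr), dim(arr))
  Tn <- model$spec$input_shape[["frames"]]
  px <- model$spec$input_shape[["h"]]
  if (dim(arr)[1] != Tn) {
    stop_cv("video frame count does not match the model input shape",
            "cognatevid_shape_error")
  }
  nb <- length(model$spec$conv_blocks)
  if (nb < 2) {
    stop_cv("model has no penultimate conv block", "cognatevid_config_error")
  }
  target <- sprintf("block%d_conv1", nb - 1)
  if (!target %in% vapply(model$arch, function(a) a$gradcam_name %||% "", "")) {
    stop_cv(sprintf("target layer %s not found", target),
            "cognatevid_config_error")
  }
  X <- assemble_batch(list(arr))
  ff <- nn_feat_fwd(model, X, train = FALSE, keep_cache = TRUE)
  Fm <- matrix(ff$out, ncol = Tn)
  hf <- nn_head_fwd(model, Fm, 1L, Tn, keep_cache = TRUE)
  dLogits <- matrix(0, 2, 1)
  dLogits[match(class, model$classes), 1] <- 1
  hb <- nn_head_bwd(model, hf$cache, dLogits)
  dOut <- hb$dF
  dim(dOut) <- dim(ff$out)
  fb <- nn_feat_bwd(model, ff$cache, dOut, capture = target)
  dA <- fb$conv_dA[[target]]              # (h, w, C, T)
  li <- which(vapply(model$arch, function(a) identical(a$gradcam_name, target), TRUE))
  A <- ff$cache[[li]]$y                   # post-ReLU activations
  hh <- dim(A)[1]; ww <- dim(A)[2]; C <- dim(A)[3]
  maps <- array(0, c(Tn, px, px))
  raw_maps <- vector("list", Tn)
  mx <- 0
  for (t in seq_len(Tn)) {
    alpha <- apply(dA[, , , t, drop = FALSE], 3, mean)
    L <- matrix(0, hh, ww)
    for (k in seq_len(C)) L <- L + alpha[k] * A[, , k, t]
    L <- pmax(L, 0)
    raw_maps[[t]] <- L
    mx <- max(mx, max(L))
  }
  if (mx > 0) {
    for (t in seq_len(Tn)) {
      maps[t, , ] <- bilinear_upsample(raw_maps[[t]] / mx, px, px)
    }
  }
  structure(maps, class = "gradcam_map", target_layer = target)
}
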