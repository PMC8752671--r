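# Training protocol, dataset splitting, augmentation, prediction and model
# persistence for the CNN-LSTM binary classifier.

#' Training configuration
#'
#' @param split Train/validation/test fractions (must sum to 1; default the
#'   published 80/10/10).
#' @param shift_augment_max Maximum augmentation shift in px (whole-video
#'   horizontal/vertical translation); 0 disables augmentation.
#' @param seed Seed controlling the split, shuffling, dropout and
#'   augmentation.
#' @param batch_size Minibatch size.
#' @param augment Apply shift augmentation to training videos.
#' @param restore_best Restore the weights of the epoch with the lowest
#'   validation loss when training ends (the standard use of the validation
#'   split; final-epoch weights are kept when `FALSE`).
#' @return A `train_config` list.
#' @export
train_config <- function(split = c(0.8, 0.1, 0.1), shift_augment_max = 10L,
                         seed = 1L, batch_size = 16L, augment = TRUE,
                         restore_best = TRUE) {
  stopifnot(length(split) == 3, abs(sum(split) - 1) < 1e-8,
            shift_augment_max >= 0, shift_augment_max < 101 / 2,
            is_count(batch_size))
  structure(list(split = split, shift_augment_max = as.integer(shift_augment_max),
                 seed = as.integer(seed), batch_size = as.integer(batch_size),
                 augment = isTRUE(augment), restore_best = isTRUE(restore_best)),
            class = "train_config")
}

# Largest-remainder seat allocation of n into fractions, ties resolved in
# order (train first).
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  seats <- floor(quota)
  left <- n - sum(seats)
  if (left > 0) {
    ord <- order(-(quota - seats), seq_along(fractions))
    seats[ord[seq_len(left)]] <- seats[ord[seq_len(left)]] + 1
  }
  as.integer(seats)
}

#' Stratified train/validation/test split
#'
#' Disjoint, exhaustive, label-stratified partition of video indices,
#' deterministic under the configuration seed. Overall split sizes follow the
#' largest-remainder rule on the configured fractions; per-class allocations
#' are balanced against those totals.
#'
#' @param labels Character vector of `"cognate"` / `"non-cognate"` labels.
#' @param cfg A [train_config()].
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, cfg = train_config()) {
  if (length(labels) < 10) {
    stop_cv("need at least 10 videos to split", "cognatevid_split_error")
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop_cv("both labels must be present to stratify", "cognatevid_split_error")
  }
  totals <- largest_remainder(length(labels), cfg$split)
  # per-(class, split) floors, then hand out remaining seats by largest
  # fractional remainder subject to both class sizes and split totals
  nclass <- vapply(classes, function(cl) sum(labels == cl), 0)
  quota <- outer(nclass, cfg$split)
  seats <- floor(quota)
  rem <- quota - seats
  row_left <- nclass - rowSums(seats)
  col_left <- totals - colSums(seats)
  ord <- order(-as.vector(t(rem)))        # remainder desc, then split, class
  for (cell in ord) {
    s <- (cell - 1) %% 3 + 1
    ci <- (cell - 1) %/% 3 + 1
    while (row_left[ci] > 0 && col_left[s] > 0) {
      seats[ci, s] <- seats[ci, s] + 1
      row_left[ci] <- row_left[ci] - 1
      col_left[s] <- col_left[s] - 1
      if (rem[ci, s] < 1) break
    }
  }
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(seed_child(cfg$seed, 11L), function() {
    for (ci in seq_along(classes)) {
      idx <- sample(which(labels == classes[ci]))
      k <- cumsum(seats[ci, ])
      out$train <<- c(out$train, idx[seq_len(k[1])])
      if (seats[ci, 2] > 0) out$val <<- c(out$val, idx[(k[1] + 1):k[2]])
      if (seats[ci, 3] > 0) out$test <<- c(out$test, idx[(k[2] + 1):k[3]])
    }
  })
  lapply(out, function(i) sort(unname(i)))
}

#' Shift-augment a cell video
#'
#' Translates every frame of the video by the same random horizontal and
#' vertical offset (at most `max_shift` px each), zero-filling vacated pixels;
#' binary input stays binary. Applying one shift to all frames preserves the
#' motion cues the classifier relies on.
#'
#' @param video A [cell_video()].
#' @param max_shift Maximum absolute shift per axis, px.
#' @return The shifted `cell_video`.
#' @export
augment_video <- function(video, max_shift = 10L) {
  dx <- sample(-max_shift:max_shift, 1)
  dy <- sample(-max_shift:max_shift, 1)
  arr <- video_numeric(video)
  a <- aperm(arr, c(2, 3, 4, 1))
  a <- shift_hwct(a, dy, dx)
  out <- video
  out$data <- array(as.raw(aperm(a, c(4, 1, 2, 3))), dim(video$data))
  out$provenance$augment_shift <- c(dy = dy, dx = dx)
  out
}

label_onehot <- function(labels, classes) {
  Y <- matrix(0, 2, length(labels))
  Y[cbind(match(labels, classes), seq_along(labels))] <- 1
  Y
}

# Extract (T,H,W,C) arrays from a list of cell_video objects (or pass raw
# arrays through).
video_arrays <- function(videos) {
  lapply(videos, function(v) if (inherits(v, "cell_video")) v$data else v)
}

eval_split <- function(model, videos, labels, batch_size) {
  probs <- predict_proba(model, videos, batch_size = batch_size)
  Y <- labels == "cognate"
  eps <- 1e-12
  loss <- -mean(log(pmax(ifelse(Y, probs, 1 - probs), eps)))
  acc <- mean((probs > 0.5) == Y)
  c(loss = loss, acc = acc)
}

#' Train the CNN-LSTM classifier
#'
#' RMSprop on 2-class cross-entropy for `spec$epochs` epochs with optional
#' whole-video shift augmentation; per-epoch training and validation loss and
#' accuracy are recorded. Training is deterministic under
#' `cfg$seed` (single-threaded) when augmentation and dropout draws are the
#' only stochastic elements.
#'
#' @param model An untrained (or partially trained) [build_model()] output.
#' @param train,val Lists with `videos` (list of [cell_video()] or binary
#'   `(T, H, W, 3)` arrays) and `labels` (character).
#' @param cfg A [train_config()].
#' @return List with the trained `model` and a `history` data frame.
#' @export
train_model <- function(model, train, val, cfg = train_config()) {
  stopifnot(length(train$videos) >= 1, length(val$videos) >= 1)
  spec <- model$spec
  Tn <- spec$input_shape[["frames"]]
  tr_videos <- video_arrays(train$videos)
  va_videos <- video_arrays(val$videos)
  if (dim(tr_videos[[1]])[1] != Tn) {
    stop_cv(sprintf("videos have %d frames but the model expects %d",
                    dim(tr_videos[[1]])[1], Tn), "cognatevid_shape_error")
  }
  Yall <- label_onehot(train$labels, model$classes)
  n <- length(tr_videos)
  history <- NULL
  best <- list(loss = Inf, params = NULL, bn = NULL, epoch = 0L)
  with_seed(seed_child(cfg$seed, 17L), function() {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_correct <- 0
      for (bs in seq(1, n, by = cfg$batch_size)) {
        ib <- ord[bs:min(bs + cfg$batch_size - 1, n)]
        B <- length(ib)
        shifts <- if (cfg$augment && cfg$shift_augment_max > 0) {
          matrix(sample(seq(-cfg$shift_augment_max, cfg$shift_augment_max),
                        2 * B, replace = TRUE), B, 2)
        } else NULL
        X <- assemble_batch(tr_videos[ib], shifts)
        Y <- Yall[, ib, drop = FALSE]
        step <- nn_train_step_grads(model, X, Y, B, Tn, dropout = TRUE)
        if (!is.finite(step$loss)) {
          stop_cv(sprintf("NaN/Inf loss at epoch %d (data loss %.4g): aborting",
                          ep, step$data_loss), "cognatevid_train_error")
        }
        model <<- fold_bn_updates(model, step$bn_updates)
        model <<- rmsprop_update(model, step$grads, spec$learning_rate)
        ep_loss <- ep_loss + step$data_loss * B
        pred <- apply(step$probs, 2, which.max)
        truth <- apply(Y, 2, which.max)
        ep_correct <- ep_correct + sum(pred == truth)
      }
      ev <- eval_split(model, va_videos, val$labels, cfg$batch_size)
      history <<- rbind(history,
                        data.frame(epoch = ep, loss = ep_loss / n,
                                   acc = ep_correct / n,
                                   val_loss = ev[["loss"]],
                                   val_acc = ev[["acc"]]))
      model$trained_epochs <<- model$trained_epochs + 1L
      if (cfg$restore_best && ev[["loss"]] < best$loss) {
        best <<- list(loss = ev[["loss"]], params = model$params,
                      bn = model$bn_state, epoch = ep)
      }
    }
  })
  if (cfg$restore_best && !is.null(best$params)) {
    model$params <- best$params
    model$bn_state <- best$bn
    model$best_epoch <- best$epoch
  }
  list(model = model, history = history)
}

#' Predict cognate probabilities
#'
#' Forward pass in inference mode (dropout off, batch norm on running
#' statistics). The returned value is the cognate softmax output; the
#' non-cognate output is its complement.
#'
#' @param model A trained `cnn_lstm`.
#' @param videos List of [cell_video()] or `(T, H, W, 3)` binary arrays.
#' @param batch_size Videos per forward batch.
#' @return Numeric vector of cognate probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, videos, batch_size = 16L) {
  arrs <- video_arrays(videos)
  Tn <- model$spec$input_shape[["frames"]]
  px <- model$spec$input_shape[["h"]]
  d <- dim(arrs[[1]])
  if (d[1] != Tn || d[2] != px || d[3] != px) {
    stop_cv(sprintf("video shape (%s) does not match model input (%d, %d, %d, 3)",
                    paste(d, collapse = ", "), Tn, px, px),
            "cognatevid_shape_error")
  }
  out <- numeric(length(arrs))
  ci <- which(model$classes == "cognate")
  for (bs in seq(1, length(arrs), by = batch_size)) {
    ib <- bs:min(bs + batch_size - 1, length(arrs))
    X <- assemble_batch(arrs[ib])
    ff <- nn_feat_fwd(model, X, train = FALSE, keep_cache = FALSE)
    Fm <- matrix(ff$out, ncol = length(ib) * Tn)
    hf <- nn_head_fwd(model, Fm, length(ib), Tn)
    out[ib] <- hf$probs[ci, ]
  }
  out
}

#' Save / load a trained model
#'
#' The model (weights, batch-norm state, optimizer cache) is serialized with
#' `saveRDS`; the architecture specification is additionally written to a
#' human-readable JSON sidecar. Reloading reproduces predictions exactly.
#'
#' @param model A `cnn_lstm`.
#' @param path Checkpoint path (an `.rds` file); the sidecar is
#'   `paste0(path, ".json")`.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$spec), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cnn_lstm")) {
    stop_cv("file does not contain a cnn_lstm model", "cognatevid_io_error")
  }
  model
}
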