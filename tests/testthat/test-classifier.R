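# CNN-LSTM construction, gradients, training protocol, persistence.

tiny_spec <- function(frames = 3L) {
  model_spec(frames = frames, input_px = 9L,
             conv_blocks = list(c(2L, 2L), c(3L)), pool_stride = 2L,
             lstm_units = 4L, dense_units = 5L, epochs = 2L,
             learning_rate = 1e-3)
}

rand_videos <- function(n, frames = 3L, px = 9L, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    array(as.raw(rbinom(frames * px * px * 3, 1, 0.2)), c(frames, px, px, 3))
  })
}

test_that("layer parameter counts match the closed forms", {
  counts <- model_param_counts(model_spec())
  expect_identical(counts[["block1_conv1"]], 3L * 3L * 3L * 8L + 8L)  # 224
  expect_identical(counts[["block1_conv2"]], 9L * 8L * 4L + 4L)
  expect_identical(counts[["block4_conv1"]], 9L * 16L * 64L + 64L)
  # pool 2x2 stride 1 shrinks 101 by one per block: flatten = 97*97*64
  expect_identical(counts[["lstm"]], 4L * 100L * (97L * 97L * 64L + 100L + 1L))
  expect_identical(counts[["softmax"]], 100L * 2L + 2L)
  # a built model's arrays agree with the closed form (small spec)
  sp <- tiny_spec()
  m <- build_model(sp, seed = 1)
  cs <- model_param_counts(sp)
  expect_identical(length(m$params$conv1.W) + length(m$params$conv1.b),
                   cs[["block1_conv1"]])
  expect_identical(length(m$params$lstm.Wx) + length(m$params$lstm.Wh) +
                     length(m$params$lstm.b), cs[["lstm"]])
})

test_that("softmax outputs are probabilities for any input", {
  m <- build_model(tiny_spec(), seed = 2)
  vids <- rand_videos(4)
  X <- cognatevid:::assemble_batch(cognatevid:::video_arrays(vids))
  ff <- cognatevid:::nn_feat_fwd(m, X, train = FALSE)
  hf <- cognatevid:::nn_head_fwd(m, matrix(ff$out, ncol = 12), 4L, 3L)
  expect_true(all(hf$probs >= 0 & hf$probs <= 1))
  expect_equal(colSums(hf$probs), rep(1, 4), tolerance = 1e-6)
  p <- predict_proba(m, vids)
  expect_true(all(p >= 0 & p <= 1))
  # duplicated video gives identical probability
  p2 <- predict_proba(m, vids[c(1, 1)])
  expect_identical(p2[1], p2[2])
})

test_that("frame-count mismatch raises a shape error", {
  m <- build_model(tiny_spec(frames = 3L), seed = 2)
  bad <- rand_videos(1, frames = 5L)
  expect_error(predict_proba(m, bad), class = "cognatevid_shape_error")
  expect_error(grad_cam(m, bad[[1]]), class = "cognatevid_shape_error")
})

test_that("analytic gradients match finite differences", {
  sp <- tiny_spec()
  m <- build_model(sp, seed = 5)
  set.seed(99)
  B <- 2L; Tn <- 3L
  X <- array(runif(9 * 9 * 3 * B * Tn), c(9, 9, 3, B * Tn))
  Y <- matrix(0, 2, B); Y[1, 1] <- 1; Y[2, 2] <- 1
  step <- cognatevid:::nn_train_step_grads(m, X, Y, B, Tn, dropout = FALSE)
  loss_fn <- function(mm) {
    cognatevid:::nn_train_step_grads(mm, X, Y, B, Tn, dropout = FALSE)$loss
  }
  eps <- 1e-5
  set.seed(7)
  for (nm in names(step$grads)) {
    g <- step$grads[[nm]]
    p <- m$params[[nm]]
    for (i in sort(sample(length(p), min(4, length(p))))) {
      m2 <- m
      m2$params[[nm]][i] <- p[i] + eps
      lp <- loss_fn(m2)
      m2$params[[nm]][i] <- p[i] - eps
      lm <- loss_fn(m2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("split_dataset is stratified, exhaustive and deterministic", {
  labs <- rep(c("cognate", "non-cognate"), each = 50)
  cfg <- train_config(seed = 3)
  sp <- split_dataset(labs, cfg)
  expect_identical(lengths(sp), c(train = 80L, val = 10L, test = 10L))
  all_idx <- sort(unname(unlist(sp)))
  expect_identical(all_idx, 1:100)
  for (part in sp) {
    expect_equal(sum(labs[part] == "cognate"), length(part) / 2)
  }
  expect_identical(split_dataset(labs, cfg), sp)
  expect_false(identical(split_dataset(labs, train_config(seed = 4)), sp))
  # 10 videos: 8/1/1 by largest remainder
  labs10 <- rep(c("cognate", "non-cognate"), each = 5)
  sp10 <- split_dataset(labs10, cfg)
  expect_identical(lengths(sp10), c(train = 8L, val = 1L, test = 1L))
  expect_error(split_dataset(rep("cognate", 20), cfg),
               class = "cognatevid_split_error")
  expect_error(split_dataset(labs10[1:4], cfg), class = "cognatevid_split_error")
})

test_that("augmentation shifts whole videos and preserves binarity", {
  v <- rand_videos(1, frames = 4L, px = 21L)[[1]]
  cv <- structure(list(data = v, cell_id = 1L, label = "cognate",
                       provenance = list(sampling_mode = "consecutive",
                                         source_frames = 0:3)),
                  class = "cell_video")
  set.seed(1)
  out <- augment_video(cv, max_shift = 5L)
  expect_identical(dim(out$data), dim(cv$data))
  expect_true(all(as.integer(out$data) %in% 0:1))
  sh <- out$provenance$augment_shift
  expect_true(all(abs(sh) <= 5))
  # the same shift applies to every frame: pixel counts only drop at borders
  a <- cognatevid:::video_numeric(cv)
  b <- cognatevid:::video_numeric(out)
  for (f in 1:4) expect_lte(sum(b[f, , , 2]), sum(a[f, , , 2]))
  # zero shift is the identity
  arr <- cognatevid:::shift_hwct(aperm(a, c(2, 3, 4, 1)), 0, 0)
  expect_equal(arr, aperm(a, c(2, 3, 4, 1)), ignore_attr = FALSE,
               tolerance = 0)
})

test_that("training learns a separable toy problem deterministically", {
  # class 1: bright moving block in both channels (overlap), class 0: empty-ish
  set.seed(11)
  mk <- function(lab) {
    a <- array(0L, c(3, 9, 9, 3))
    if (lab == "cognate") {
      for (f in 1:3) a[f, (2:5) + f %% 2, 2:5, 1:2] <- 1L
    } else {
      for (f in 1:3) a[f, sample(7, 1) + 0:1, sample(7, 1) + 0:1, 2] <- 1L
    }
    array(as.raw(a), dim(a))
  }
  labs <- rep(c("cognate", "non-cognate"), each = 10)
  vids <- lapply(labs, mk)
  sp <- tiny_spec()
  sp$epochs <- 10L
  sp$learning_rate <- 5e-3
  cfg <- train_config(seed = 2, augment = FALSE, batch_size = 8L)
  m <- build_model(sp, seed = 3)
  fit <- train_model(m, list(videos = vids, labels = labs),
                     list(videos = vids[c(1, 11)], labels = labs[c(1, 11)]),
                     cfg)
  expect_identical(nrow(fit$history), 10L)
  # optimization sanity: loss decreases on separable data
  expect_lt(fit$history$loss[10], fit$history$loss[1])
  p <- predict_proba(fit$model, vids)
  expect_gt(mean(p[labs == "cognate"]), mean(p[labs == "non-cognate"]))
  # same seeds, same data -> identical history and predictions
  fit2 <- train_model(build_model(sp, seed = 3),
                      list(videos = vids, labels = labs),
                      list(videos = vids[c(1, 11)], labels = labs[c(1, 11)]),
                      cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(predict_proba(fit2$model, vids), p)
})

test_that("save/load reproduces predictions bit for bit", {
  m <- build_model(tiny_spec(), seed = 6)
  vids <- rand_videos(3, seed = 8)
  p1 <- predict_proba(m, vids)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_proba(m2, vids), p1)
  expect_true(file.exists(paste0(path, ".json")))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$lstm_units, m$spec$lstm_units)
})

test_that("grad_cam maps are normalized, correctly shaped and rectified", {
  sp <- tiny_spec()
  m <- build_model(sp, seed = 9)
  v <- rand_videos(1, seed = 12)[[1]]
  g <- grad_cam(m, v, class = "cognate")
  expect_identical(dim(unclass(g)), c(3L, 9L, 9L))
  expect_true(all(g >= 0 & g <= 1))
  expect_true(max(g) == 1 || all(g == 0))
  expect_identical(attr(g, "target_layer"), "block1_conv1")
  # all-zero input on an untrained model: zero or uniform map, never NaN
  z <- array(as.raw(0L), c(3, 9, 9, 3))
  gz <- grad_cam(m, z)
  expect_false(any(is.na(gz)))
})
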