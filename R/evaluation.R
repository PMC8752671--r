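# ROC/AUC evaluation, metric-vs-model comparison, cross-population
# generalization and the frame-count ablation experiment.

# Orientation of each classical metric, fixed a priori from the biology of
# cognate contacts (not post hoc from the data): stable synapses mean more
# overlap, more DC pixels in the crop and more time in contact, but lower
# speed and lower circularity.
METRIC_ORIENTATION <- c(mean_overlap_px = "higher_is_cognate",
                        mean_red_px = "higher_is_cognate",
                        interaction_pct = "higher_is_cognate",
                        mean_speed = "lower_is_cognate",
                        mean_circularity = "lower_is_cognate")

#' ROC curve and AUC
#'
#' Sweeps all score thresholds and integrates the ROC curve by the trapezoid
#' rule, which equals the probability that a random cognate cell outscores a
#' random non-cognate cell with ties counted one half. For metrics where low
#' values indicate cognate interactions (speed, circularity) use
#' `orientation = "lower_is_cognate"`, which negates the scores first.
#'
#' @param scores Numeric scores, one per cell.
#' @param labels `"cognate"` / `"non-cognate"` labels.
#' @param orientation Score direction.
#' @return A `roc_curve`: `thresholds`, `fpr`, `tpr`, `auc`,
#'   `positive_class`, `score_orientation`.
#' @export
roc_auc <- function(scores, labels,
                    orientation = c("higher_is_cognate", "lower_is_cognate")) {
  orientation <- match.arg(orientation)
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores))) {
    stop_cv("scores must be finite", "cognatevid_roc_error")
  }
  pos <- labels == "cognate"
  if (all(pos) || !any(pos)) {
    stop_cv("both classes must be present to compute a ROC curve",
            "cognatevid_roc_error")
  }
  s <- if (orientation == "lower_is_cognate") -scores else scores
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; pos <- pos[ord]
  # group ties so tied scores move along the curve together
  grp <- cumsum(!duplicated(s))
  tp <- tapply(pos, grp, sum)
  fp <- tapply(!pos, grp, sum)
  tpr <- c(0, cumsum(tp) / sum(pos))
  fpr <- c(0, cumsum(fp) / sum(!pos))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, s[!duplicated(s)]),
                 fpr = as.numeric(fpr), tpr = as.numeric(tpr),
                 auc = as.numeric(auc),
                 positive_class = "cognate",
                 score_orientation = orientation),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%s, positive = %s, %d thresholds)\n",
              x$auc, x$score_orientation, x$positive_class,
              length(x$thresholds)))
  invisible(x)
}

#' Simulate, process and summarize a labelled benchmark dataset
#'
#' Simulates `n_fields_per_class` fields per condition (all-cognate and
#' all-non-cognate wells), runs every ground-truth track through the per-cell
#' video pipeline over all frames, and returns the processed full-length
#' binary videos together with classical metric summaries. Sampled videos for
#' the classifier are sliced from the stored full-length videos with
#' [sample_frames()] rules via `dataset_videos()`.
#'
#' @param params A [sim_params()].
#' @param n_fields_per_class Fields simulated per condition.
#' @param acd40 Apply the aCD40 multipliers.
#' @param pp A [pipeline_params()] (its sampling settings are not used here;
#'   all frames are processed).
#' @param seed Master seed for the simulated fields.
#' @param with_circularity Compute the (relatively expensive) per-frame
#'   circularity metric; when `FALSE` the column is `NA`.
#' @return A `cv_dataset`: `videos` (full-length processed videos), `tracks`,
#'   `labels`, `metrics` (per-cell data frame), `params`.
#' @export
build_dataset <- function(params = sim_params(), n_fields_per_class = 2L,
                          acd40 = TRUE, pp = pipeline_params(), seed = 1L,
                          with_circularity = TRUE) {
  videos <- list(); tracks <- list(); labels <- character(0)
  metrics <- NULL
  for (label in c("cognate", "non-cognate")) {
    for (fld in seq_len(n_fields_per_class)) {
      p <- params
      p$seed <- seed_child(seed, c(match(label, c("cognate", "non-cognate")), fld))
      sim <- simulate_field(p, label = label, acd40 = acd40)
      thr <- field_dc_threshold(sim$stack, pp$blur_sigma)
      for (tr in filter_min_length(sim$truth$tracks, 20L)) {
        cvf <- .cell_video_at(sim$stack, tr, pp,
                              sel0 = seq_len(nrow(tr$points)) - 1L,
                              dc_threshold = thr)
        cvf$cell_id <- length(videos) + 1L
        videos[[length(videos) + 1L]] <- cvf
        tr$cell_id <- cvf$cell_id
        tracks[[length(tracks) + 1L]] <- tr
        labels <- c(labels, label)
        metrics <- rbind(metrics,
                         summarize_cell(cvf, tr, p$frame_interval, p$pixel_size,
                                        with_circularity = with_circularity))
      }
    }
  }
  structure(list(videos = videos, tracks = tracks, labels = labels,
                 metrics = metrics, params = params, acd40 = acd40),
            class = "cv_dataset")
}

#' Slice classifier-input videos out of a dataset
#'
#' @param dataset A [build_dataset()] result.
#' @param mode,k Sampling rule passed to [sample_frames()].
#' @param downsample Spatial subsampling factor (see [downsample_video()]).
#' @return List of fixed-length [cell_video()] objects.
#' @export
dataset_videos <- function(dataset, mode = c("uniform", "consecutive"),
                           k = 20L, downsample = 1L) {
  mode <- match.arg(mode)
  lapply(dataset$videos, function(cv) {
    idx <- sample_frames(dim(cv$data)[1], mode = mode, k = k)
    downsample_video(subset_cell_video(cv, idx, mode), downsample)
  })
}

# Train on the train+aug split and return test-set scores plus the model.
# A run whose best validation loss is poor is retrained (up to `restarts`
# times) from a different initialization and the best-validation model is
# kept: model selection uses only train/val, never the test split.
train_and_score <- function(dataset, spec, cfg, mode = "uniform", k = 20L,
                            downsample = 1L, subset = NULL, restarts = 1L) {
  if (!is.null(subset)) {
    dataset$videos <- dataset$videos[subset]
    dataset$labels <- dataset$labels[subset]
    dataset$metrics <- dataset$metrics[subset, ]
  }
  vids <- dataset_videos(dataset, mode = mode, k = k, downsample = downsample)
  parts <- split_dataset(dataset$labels, cfg)
  train <- list(videos = vids[parts$train], labels = dataset$labels[parts$train])
  val <- list(videos = vids[parts$val], labels = dataset$labels[parts$val])
  best <- NULL
  for (try in 0:restarts) {
    cfg_try <- cfg
    cfg_try$seed <- seed_child(cfg$seed, c(29L, try))
    model <- build_model(spec, seed = seed_child(cfg$seed, c(23L, try)))
    fit <- train_model(model, train, val, cfg_try)
    fit$val_loss <- min(fit$history$val_loss)
    if (is.null(best) || fit$val_loss < best$val_loss) best <- fit
    if (best$val_loss < 0.45) break      # converged run; no restart needed
  }
  probs <- predict_proba(best$model, vids[parts$test],
                         batch_size = cfg$batch_size)
  list(model = best$model, history = best$history, parts = parts,
       test_probs = probs, test_labels = dataset$labels[parts$test],
       test_videos = vids[parts$test])
}

#' Compare the deep model with the classical metrics
#'
#' Trains the classifier once per seed and computes the AUC of the deep model
#' and of each classical metric on the same held-out test cells, with metric
#' orientations fixed a priori.
#'
#' @param dataset A [build_dataset()] result.
#' @param spec A [model_spec()] (default the desk-scale benchmark spec).
#' @param cfg A [train_config()]; its seed is re-derived per repeat.
#' @param seeds Integer seeds for the stochastic repeats.
#' @param downsample Spatial subsampling factor for the classifier inputs.
#' @return Data frame of AUCs (one row per method) with per-seed columns and
#'   their mean.
#' @export
compare_methods <- function(dataset, spec = model_spec_small(),
                            cfg = train_config(), seeds = 1:5,
                            downsample = 1L) {
  methods <- c("deep_learning", names(METRIC_ORIENTATION))
  res <- matrix(NA_real_, length(methods), length(seeds),
                dimnames = list(methods, paste0("seed", seeds)))
  for (si in seq_along(seeds)) {
    cfg$seed <- as.integer(seeds[si])
    ts <- train_and_score(dataset, spec, cfg, downsample = downsample)
    res["deep_learning", si] <- roc_auc(ts$test_probs, ts$test_labels)$auc
    mt <- dataset$metrics[ts$parts$test, ]
    for (m in names(METRIC_ORIENTATION)) {
      res[m, si] <- roc_auc(mt[[m]], ts$test_labels,
                            orientation = METRIC_ORIENTATION[[m]])$auc
    }
  }
  out <- data.frame(method = methods, res, mean_auc = rowMeans(res),
                    row.names = NULL, check.names = FALSE)
  out
}

#' Frame-count ablation
#'
#' For each frame count `k`, slices the first `k` consecutive frames out of
#' every video, trains a fresh model per seed and reports the seed-averaged
#' held-out AUC, mirroring the observation that classification degrades as
#' temporal context shrinks.
#'
#' @param dataset A [build_dataset()] result with videos of >= 20 frames.
#' @param counts Consecutive frame counts to test.
#' @param spec Base [model_spec()]; its frame count is overridden per run.
#' @param cfg A [train_config()].
#' @param seeds Seeds for the stochastic repeats.
#' @param downsample Spatial subsampling factor for the classifier inputs.
#' @param subset Optional index subset of the dataset's cells.
#' @return An `ablation_result` data frame: one row per (count, seed) plus
#'   seed-averaged AUCs in `attr(, "summary")`.
#' @export
run_ablation <- function(dataset, counts = c(20L, 10L, 5L, 2L),
                         spec = model_spec_small(), cfg = train_config(),
                         seeds = 1:5, downsample = 1L, subset = NULL) {
  rows <- NULL
  for (k in counts) {
    sk <- spec
    sk$input_shape[["frames"]] <- as.integer(k)
    for (sd in seeds) {
      cfg$seed <- as.integer(sd)
      ts <- train_and_score(dataset, sk, cfg, mode = "consecutive", k = k,
                            downsample = downsample, subset = subset)
      rows <- rbind(rows, data.frame(frames = k, seed = sd,
                                     auc = roc_auc(ts$test_probs,
                                                   ts$test_labels)$auc))
    }
  }
  summary <- aggregate(auc ~ frames, rows, mean)
  structure(rows, class = c("ablation_result", "data.frame"),
            summary = summary)
}

#' Evaluate a trained model on a different population
#'
#' Applies the model without any weight adjustment to videos from another
#' simulated population (e.g. a lower-affinity peptide or another TCR
#' transgenic strain, via [sim_params_preset()]) and returns the ROC curve.
#'
#' @param model A trained `cnn_lstm`.
#' @param dataset A [build_dataset()] result for the other population.
#' @param mode,k Sampling rule for slicing classifier inputs.
#' @param downsample Spatial subsampling factor (must match the model input).
#' @return A `roc_curve`.
#' @export
cross_population_eval <- function(model, dataset, mode = "uniform", k = 20L,
                                  downsample = 1L) {
  vids <- dataset_videos(dataset, mode = mode, k = k, downsample = downsample)
  probs <- predict_proba(model, vids)
  roc_auc(probs, dataset$labels)
}

#' @export
print.cv_dataset <- function(x, ...) {
  cat(sprintf("<cv_dataset> %d cells (%d cognate / %d non-cognate), %s, %d-frame videos\n",
              length(x$videos), sum(x$labels == "cognate"),
              sum(x$labels == "non-cognate"),
              if (x$acd40) "+aCD40" else "-aCD40",
              dim(x$videos[[1]]$data)[1]))
  invisible(x)
}
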