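# Shared fixtures: small binary shapes, tiny simulated stacks, and a memoized
# benchmark dataset reused across the acceptance criteria so the expensive
# simulation + preprocessing runs once per test session.

rasterized_disk <- function(r, pad = 3L) {
  n <- 2L * r + 2L * pad + 1L
  c0 <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

filled_square <- function(side, pad = 3L) {
  n <- side + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

# Brute-force Otsu oracle: exhaustive scan of between-class variance with the
# same midpoint-of-tied-plateau convention as the implementation contract.
otsu_oracle <- function(hist) {
  n <- sum(hist)
  best <- -Inf; ties <- integer(0)
  for (t in 0:254) {
    w0 <- sum(hist[1:(t + 1)]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(hist[1:(t + 1)] * (0:t)) / w0
    mu1 <- sum(hist[(t + 2):256] * ((t + 1):255)) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-10 * max(best, 1)) {
      best <- bcv; ties <- t
    } else if (abs(bcv - best) <= 1e-10 * max(best, 1)) {
      ties <- c(ties, t)
    }
  }
  as.integer(floor(mean(ties)))
}

# Brute-force Huang fuzzy-entropy oracle (explicit loops, no cumulants).
huang_oracle <- function(hist) {
  lev <- 0:255
  pop <- which(hist > 0)
  if (length(pop) == 1) return(lev[pop])
  gmin <- lev[pop[1]]; gmax <- lev[pop[length(pop)]]
  C <- gmax - gmin
  hf <- function(u) {
    if (u <= 0 || u >= 1) return(0)
    -u * log(u) - (1 - u) * log(1 - u)
  }
  ent <- rep(Inf, 255)
  for (t in 0:254) {
    w0 <- sum(hist[1:(t + 1)]); w1 <- sum(hist) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(hist[1:(t + 1)] * (0:t)) / w0
    mu1 <- sum(hist[(t + 2):256] * ((t + 1):255)) / w1
    s <- 0
    for (g in 0:255) {
      if (hist[g + 1] == 0) next
      mu <- if (g <= t) mu0 else mu1
      u <- 1 / (1 + abs(g - mu) / C)
      s <- s + hist[g + 1] * hf(u)
    }
    ent[t + 1] <- s
  }
  mn <- min(ent)
  as.integer(floor(mean(which(ent <= mn + 1e-10 * max(abs(mn), 1)) - 1L)))
}

# Pairwise-concordance AUC oracle: P(cognate outscores non-cognate), ties 1/2.
concordance_oracle <- function(scores, labels) {
  sp <- scores[labels == "cognate"]
  sn <- scores[labels != "cognate"]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Small fast simulation parameters for unit tests.
test_sim_params <- function(...) {
  args <- utils::modifyList(list(field_px = 220L, n_frames = 25L,
                                 n_tcells = 3L, n_dcs = 8L, noise_sd = 4),
                            list(...))
  do.call(sim_params, args)
}

# ---- memoized benchmark dataset for the acceptance criteria ----------------
.acc_env <- new.env(parent = emptyenv())

# 25 fields/class x 8 T cells = 200 cells per class at default +aCD40
# parameters (criterion 4: metric directions).
acceptance_data <- function() {
  if (is.null(.acc_env$data)) {
    .acc_env$data <- build_dataset(sim_params(), n_fields_per_class = 25L,
                                   acd40 = TRUE, seed = 2024L)
  }
  .acc_env$data
}

# The wide-parameter-gap ("separable") benchmark co-culture used by the
# classifier criteria (5-7); circularity is not needed there.
acceptance_benchmark_data <- function() {
  if (is.null(.acc_env$bench)) {
    .acc_env$bench <- build_dataset(sim_params_preset("separable"),
                                    n_fields_per_class = 25L, acd40 = TRUE,
                                    seed = 2024L, with_circularity = FALSE)
  }
  .acc_env$bench
}

# Downsampled (34 px) 20-frame uniform videos of the benchmark dataset.
acceptance_videos_small <- function() {
  if (is.null(.acc_env$vids34)) {
    .acc_env$vids34 <- dataset_videos(acceptance_benchmark_data(), "uniform",
                                      20L, downsample = 3L)
  }
  .acc_env$vids34
}

acceptance_benchmark_spec <- function(frames = 20L, epochs = 16L) {
  sp <- model_spec_small(frames = frames, epochs = epochs)
  sp$input_shape[["h"]] <- sp$input_shape[["w"]] <- 34L
  sp
}

acceptance_train_config <- function(seed) {
  train_config(seed = seed, shift_augment_max = 1L)  # ~3 px at full scale
}

# Train the scaled benchmark classifier for one seed; memoized so the
# classifier-benchmark, Grad-CAM and determinism criteria share models.
acceptance_fit <- function(seed) {
  key <- paste0("fit", seed)
  if (is.null(.acc_env[[key]])) {
    ts <- cognatevid:::train_and_score(acceptance_benchmark_data(),
                                       acceptance_benchmark_spec(),
                                       acceptance_train_config(seed),
                                       downsample = 3L)
    .acc_env[[key]] <- list(model = ts$model, history = ts$history,
                            parts = ts$parts, probs = ts$test_probs,
                            labels = ts$test_labels)
  }
  .acc_env[[key]]
}
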