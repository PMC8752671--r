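# Per-cell video pipeline: crop geometry, frame sampling, thresholding,
# masking and binarization.

test_that("crop_window centers odd windows and clamps at borders", {
  expect_equal(crop_window(c(300, 200), c(512, 512), 101),
               list(row_lo = 150L, row_hi = 251L, col_lo = 250L, col_hi = 351L))
  expect_equal(crop_window(c(300, 10), c(512, 512), 101),
               list(row_lo = 0L, row_hi = 101L, col_lo = 250L, col_hi = 351L))
  expect_equal(crop_window(c(511, 511), c(512, 512), 101),
               list(row_lo = 411L, row_hi = 512L, col_lo = 411L, col_hi = 512L))
  # clamped or not, the window is always exactly crop_px wide
  for (x in c(0, 3, 50.4, 50.5, 255.7, 500, 511)) {
    w <- crop_window(c(x, x), c(512, 512), 101)
    expect_equal(w$row_hi - w$row_lo, 101L)
    expect_equal(w$col_hi - w$col_lo, 101L)
    expect_gte(w$row_lo, 0L)
    expect_lte(w$row_hi, 512L)
  }
  expect_error(crop_window(c(10, 10), c(64, 64), 101),
               class = "cognatevid_sizing_error")
})

test_that("sample_frames follows the published stride rules", {
  expect_identical(sample_frames(45), seq(0L, 38L, by = 2L))
  expect_identical(sample_frames(61), seq(0L, 57L, by = 3L))
  expect_identical(sample_frames(20), 0:19)
  expect_error(sample_frames(19), class = "cognatevid_exclusion_error")
  expect_identical(sample_frames(30, "consecutive", k = 5L), 0:4)
  expect_error(sample_frames(4, "consecutive", k = 5L),
               class = "cognatevid_exclusion_error")
})

test_that("uniform sampling always yields 20 increasing indices from 0", {
  for (n in 20:200) {
    s <- sample_frames(n)
    expect_length(s, 20L)
    expect_identical(s[1], 0L)
    expect_true(all(diff(s) > 0))
    expect_lt(s[20], n)
  }
})

test_that("otsu and huang thresholds match exhaustive brute-force oracles", {
  set.seed(42)
  for (i in 1:30) {
    # random bimodal-ish histograms
    h <- tabulate(pmin(pmax(round(c(rnorm(400, runif(1, 20, 90), runif(1, 3, 20)),
                                    rnorm(150, runif(1, 120, 240), runif(1, 3, 25)))),
                            0) + 1, 255) + 0, nbins = 256)
    expect_identical(otsu_threshold(h), otsu_oracle(h), label = paste("otsu", i))
    expect_identical(huang_threshold(h), huang_oracle(h), label = paste("huang", i))
  }
  # uniform histogram
  h <- rep(2L, 256)
  expect_identical(otsu_threshold(h), otsu_oracle(h))
  expect_identical(huang_threshold(h), huang_oracle(h))
})

test_that("two-delta histograms threshold between the modes; degenerate cases", {
  h <- integer(256); h[51] <- 300; h[201] <- 300   # bins 50 and 200
  t_h <- huang_threshold(h)
  expect_gt(t_h, 50); expect_lt(t_h, 200)
  t_o <- otsu_threshold(h)
  expect_gt(t_o, 10); expect_lt(t_o, 200)
  # mirrored histogram maps to the mirrored threshold
  hm <- rev(h)
  expect_equal(huang_threshold(hm), 254L - t_h, tolerance = 1)
  # single populated bin: that bin (all-background convention)
  h1 <- integer(256); h1[101] <- 50
  expect_identical(huang_threshold(h1), 100L)
  expect_identical(otsu_threshold(h1), 100L)
})

test_that("mask_neighbors removes everything outside the ROI, DC untouched", {
  cropped <- array(0, c(2, 21, 21, 3))
  cropped[, 5:8, 5:8, 2] <- 200     # tracked cell
  cropped[, 15:18, 15:18, 2] <- 200 # neighbour
  cropped[, , , 1] <- 7             # DC channel content
  roi <- matrix(FALSE, 21, 21); roi[4:9, 4:9] <- TRUE
  out <- mask_neighbors(cropped, list(roi, roi))
  expect_equal(sum(out[1, , , 2] > 0), 16)       # neighbour removed
  expect_identical(out[, , , 1], cropped[, , , 1])
  # full-frame ROI is the identity
  full <- matrix(TRUE, 21, 21)
  expect_identical(mask_neighbors(cropped, list(full, full)), cropped)
  # empty ROI zeroes the channel with a warning
  expect_warning(out0 <- mask_neighbors(cropped, list(full, matrix(FALSE, 21, 21))),
                 "empty ROI")
  expect_true(all(out0[2, , , 2] == 0))
})

test_that("binarize recovers rendered shapes and is idempotent", {
  # noiseless frame: foreground 200, background 0
  cropped <- array(0, c(1, 41, 41, 3))
  disk <- rasterized_disk(8, pad = 12)
  cropped[1, , , 2] <- ifelse(disk, 200, 0)
  cropped[1, 10:20, 10:20, 1] <- 200
  out <- binarize(cropped, dc_threshold = 100, blur_sigma = 1)
  expect_true(all(out %in% 0:1))
  # mask equals the rendered disk within a blur-halo boundary tolerance
  diffpx <- which(out[1, , , 2] != disk, arr.ind = TRUE)
  if (nrow(diffpx) > 0) {
    c0 <- (41 + 1) / 2
    rad <- sqrt((diffpx[, 1] - c0)^2 + (diffpx[, 2] - c0)^2)
    expect_true(all(abs(rad - 8) <= 1.5))
  }
  # all-zero DC channel stays all zero
  expect_true(all(out[1, , , 1][cropped[1, , , 1] == 0] %in% 0:1))
  zero <- array(0, c(1, 41, 41, 3))
  expect_warning(out0 <- binarize(zero, dc_threshold = 100),
                 "constant T-cell channel")
  expect_true(all(out0 == 0))
  # idempotence: binarizing an already-binary video changes nothing
  bin255 <- out
  bin255[1, , , 2] <- out[1, , , 2] * 255
  again <- binarize(bin255, dc_threshold = 100, blur_sigma = 0)
  expect_identical(again[1, , , 2], out[1, , , 2])
})

test_that("full pipeline produces exact-shape binary videos deterministically", {
  p <- test_sim_params(seed = 5)
  sim <- simulate_field(p, "cognate", acd40 = TRUE)
  thr <- field_dc_threshold(sim$stack)
  pp <- pipeline_params()
  cv1 <- cell_video(sim$stack, sim$truth$tracks[[1]], pp, thr)
  cv2 <- cell_video(sim$stack, sim$truth$tracks[[1]], pp, thr)
  expect_identical(cv1, cv2)
  expect_identical(dim(cv1$data), c(20L, 101L, 101L, 3L))
  expect_true(all(as.integer(cv1$data) %in% 0:1))
  expect_true(all(as.integer(cv1$data[, , , 3]) == 0L))
  # 25 source frames: first-20 rule (stride 1)
  expect_identical(cv1$provenance$source_frames, 0:19)
  # consecutive-k mode
  pp2 <- pipeline_params(sampling_mode = "consecutive", consecutive_k = 5L)
  cv5 <- cell_video(sim$stack, sim$truth$tracks[[2]], pp2, thr)
  expect_identical(dim(cv5$data)[1], 5L)
  expect_identical(cv5$provenance$source_frames, 0:4)
})
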