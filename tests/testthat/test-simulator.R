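# Agent-based co-culture simulator and stack I/O.

test_that("sim_params validates its invariants", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(field_px = 150), class = "cognatevid_param_error")
  expect_error(sim_params(dwell_mean_cognate = 2, dwell_mean_noncognate = 3),
               class = "cognatevid_param_error")
  expect_error(sim_params(contact_circ_cognate = 0.9,
                          contact_circ_noncognate = 0.8),
               class = "cognatevid_param_error")
  expect_error(sim_params(n_frames = 0), class = "cognatevid_param_error")
})

test_that("identical params + seed give bit-identical stacks and truth", {
  p <- test_sim_params(seed = 31)
  a <- simulate_field(p, "non-cognate", acd40 = FALSE)
  b <- simulate_field(p, "non-cognate", acd40 = FALSE)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth, b$truth)
  p2 <- test_sim_params(seed = 32)
  c <- simulate_field(p2, "non-cognate", acd40 = FALSE)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("no-DC degenerate field renders one clean T cell", {
  p <- sim_params(field_px = 210L, n_frames = 20L, n_tcells = 1L, n_dcs = 1L,
                  noise_sd = 0, seed = 3)
  p$n_dcs <- 0L
  s <- simulate_field(p, "non-cognate")
  expect_identical(dim(s$stack$data)[1], 20L)
  expect_true(all(s$stack$data[, , , 1] == 0L))     # channel 0 empty
  area <- vapply(1:20, function(f) sum(s$stack$data[f, , , 2] > 100), 0)
  expect_true(all(abs(area - pi * p$tcell_radius^2) / (pi * p$tcell_radius^2) < 0.1))
  # rendered centroids agree with ground-truth track positions within 1 px
  for (f in c(1, 10, 20)) {
    m <- s$stack$data[f, , , 2]
    px <- which(m > 0, arr.ind = TRUE)
    w <- m[px]
    cx <- sum((px[, 2] - 1) * w) / sum(w)
    cy <- sum((px[, 1] - 1) * w) / sum(w)
    expect_lt(abs(cx - s$truth$tracks[[1]]$points$x[f]), 1)
    expect_lt(abs(cy - s$truth$tracks[[1]]$points$y[f]), 1)
  }
})

test_that("ground truth is well-formed", {
  p <- test_sim_params(seed = 8)
  s <- simulate_field(p, "cognate", acd40 = TRUE)
  expect_length(s$truth$tracks, p$n_tcells)
  for (k in seq_len(p$n_tcells)) {
    pts <- s$truth$tracks[[k]]$points
    expect_identical(pts$frame, 0:(p$n_frames - 1))
    expect_true(all(pts$x >= 0 & pts$x <= p$field_px - 1))
    iv <- s$truth$contact_intervals[[k]]
    if (nrow(iv)) {
      expect_true(all(iv$start_frame <= iv$end_frame))
      expect_true(all(iv$start_frame >= 0 & iv$end_frame < p$n_frames))
      if (nrow(iv) > 1) {     # disjoint and sorted
        expect_true(all(diff(iv$start_frame) > 0))
        expect_true(all(iv$start_frame[-1] > iv$end_frame[-nrow(iv)]))
      }
    }
  }
})

test_that("cognate cells arrest and dwell longer than non-cognate cells", {
  speeds <- function(label, seed) {
    p <- test_sim_params(n_tcells = 6L, seed = seed)
    s <- simulate_field(p, label)
    vapply(s$truth$tracks, function(t) {
      d <- diff(complex(real = t$points$x, imaginary = t$points$y))
      mean(Mod(d)) * p$pixel_size / p$frame_interval
    }, 0)
  }
  cfrac <- function(label, seed) {
    p <- test_sim_params(n_tcells = 6L, seed = seed)
    s <- simulate_field(p, label)
    vapply(seq_len(p$n_tcells), function(k) {
      iv <- s$truth$contact_intervals[[k]]
      if (!nrow(iv)) 0 else sum(iv$end_frame - iv$start_frame + 1) / p$n_frames
    }, 0)
  }
  sc <- unlist(lapply(1:4, function(i) speeds("cognate", 300 + i)))
  sn <- unlist(lapply(1:4, function(i) speeds("non-cognate", 300 + i)))
  expect_lt(mean(sc), mean(sn))
  fc <- unlist(lapply(1:4, function(i) cfrac("cognate", 300 + i)))
  fn <- unlist(lapply(1:4, function(i) cfrac("non-cognate", 300 + i)))
  expect_gt(mean(fc), mean(fn))
})

test_that("field too small for the requested cell count is rejected", {
  p <- sim_params(field_px = 205L, n_tcells = 60L, n_dcs = 120L,
                  n_frames = 5L)
  expect_error(simulate_field(p, "cognate"), class = "cognatevid_sizing_error")
})

test_that("TIFF stacks round-trip bit-for-bit", {
  p <- test_sim_params(n_frames = 4L, seed = 12)
  s <- simulate_field(p, "cognate")
  tf <- tempfile(fileext = ".tif")
  write_stack(s$stack, tf)
  rt <- read_stack(tf)
  expect_identical(rt$data, s$stack$data)
  expect_identical(rt$frame_interval, s$stack$frame_interval)
  expect_identical(rt$pixel_size, s$stack$pixel_size)
  expect_identical(rt$channels, s$stack$channels)
  # single-frame stack is a valid file
  s1 <- s$stack
  s1$data <- s$stack$data[1, , , , drop = FALSE]
  tf1 <- tempfile(fileext = ".tif")
  write_stack(s1, tf1)
  expect_identical(read_stack(tf1)$data, s1$data)
  # truncated file gives a parse error naming the offending page
  bytes <- readBin(tf, "raw", file.info(tf)$size)
  tf2 <- tempfile(fileext = ".tif")
  writeBin(bytes[1:(length(bytes) %/% 3)], tf2)
  expect_error(read_stack(tf2), "page", class = "cognatevid_tiff_error")
  # not a TIFF at all
  tf3 <- tempfile()
  writeBin(charToRaw("not a tiff at all, really"), tf3)
  expect_error(read_stack(tf3), class = "cognatevid_tiff_error")
})

test_that("sim config and ground truth CSVs round-trip", {
  p <- sim_params(seed = 99, n_dcs = 12L)
  cf <- tempfile(fileext = ".cfg")
  write_sim_config(p, cf)
  p2 <- read_sim_config(cf)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)
  s <- simulate_field(test_sim_params(n_frames = 6L, seed = 2), "cognate")
  ft <- tempfile(fileext = ".csv"); fl <- tempfile(fileext = ".csv")
  write_ground_truth(s$truth, ft, fl)
  rt <- read_ground_truth(ft, fl)
  expect_length(rt$tracks, length(s$truth$tracks))
  expect_equal(rt$tracks[[1]]$points, s$truth$tracks[[1]]$points,
               tolerance = 1e-9)
  expect_identical(unname(rt$labels), unname(s$truth$labels))
})

test_that("aCD40 shortens non-cognate contacts without hurting cognate ones", {
  frac <- function(label, acd40, seeds) {
    out <- c()
    for (sd in seeds) {
      p <- test_sim_params(n_tcells = 6L, seed = sd)
      s <- simulate_field(p, label, acd40 = acd40)
      out <- c(out, vapply(seq_len(p$n_tcells), function(k) {
        iv <- s$truth$contact_intervals[[k]]
        if (!nrow(iv)) 0 else sum(iv$end_frame - iv$start_frame + 1) / p$n_frames
      }, 0))
    }
    mean(out)
  }
  seeds <- 401:406
  expect_lt(frac("non-cognate", TRUE, seeds), frac("non-cognate", FALSE, seeds))
  expect_gte(frac("cognate", TRUE, seeds) + 0.02, frac("cognate", FALSE, seeds))
})
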