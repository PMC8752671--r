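# Greedy nearest-neighbour tracker and TrackMate CSV interoperability.

# Render a minimal noiseless stack with given per-frame T cell positions.
toy_stack <- function(positions, H = 220L, nf = NULL) {
  nf <- nf %||% nrow(positions[[1]])
  data <- array(0L, c(nf, H, H, 3))
  for (f in seq_len(nf)) {
    m <- matrix(0, H, H)
    for (pos in positions) {
      if (nrow(pos) < f) next
      cognatevid:::.cpp_add_ellipse(m, pos[f, 1], pos[f, 2], 5, 5, 0, 200)
    }
    data[f, , , 2] <- as.integer(round(m))
  }
  structure(list(data = data, frame_interval = 2, pixel_size = 1,
                 channels = c("DC", "TCELL", "EMPTY")), class = "image_stack")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a single stationary cell yields one accurate track", {
  pos <- matrix(rep(c(60, 80), each = 20), ncol = 2)
  st <- toy_stack(list(pos), nf = 20L)
  tr <- track_cells(st, max_link_dist = 10)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]$points), 20)
  expect_true(all(abs(tr[[1]]$points$x - 60) <= 1))
  expect_true(all(abs(tr[[1]]$points$y - 80) <= 1))
})

test_that("well-separated cells never swap identities", {
  set.seed(4)
  nf <- 15L
  p1 <- cbind(30 + cumsum(rnorm(nf, 0, 2)), 30 + cumsum(rnorm(nf, 0, 2)))
  p2 <- cbind(180 + cumsum(rnorm(nf, 0, 2)), 180 + cumsum(rnorm(nf, 0, 2)))
  st <- toy_stack(list(p1, p2), nf = nf)
  tr <- track_cells(st, max_link_dist = 15)
  expect_length(tr, 2)
  expect_true(all(vapply(tr, function(t) nrow(t$points), 0L) == nf))
  # each recovered track stays near one ground-truth trajectory throughout
  for (t in tr) {
    d1 <- mean(sqrt((t$points$x - p1[, 1])^2 + (t$points$y - p1[, 2])^2))
    d2 <- mean(sqrt((t$points$x - p2[, 1])^2 + (t$points$y - p2[, 2])^2))
    expect_lt(min(d1, d2), 1.5)
    expect_gt(max(d1, d2), 50)
  }
})

test_that("tracker recovers simulated fields against ground truth", {
  p <- test_sim_params(n_tcells = 4L, seed = 77)
  s <- simulate_field(p, "non-cognate")
  tr <- filter_min_length(track_cells(s$stack, max_link_dist = 25), 20L)
  expect_gte(length(tr), ceiling(0.9 * p$n_tcells))
  errs <- vapply(tr, function(t) {
    min(vapply(s$truth$tracks, function(g) {
      common <- intersect(t$points$frame, g$points$frame)
      i1 <- match(common, t$points$frame); i2 <- match(common, g$points$frame)
      mean(sqrt((t$points$x[i1] - g$points$x[i2])^2 +
                (t$points$y[i1] - g$points$y[i2])^2))
    }, 0))
  }, 0)
  expect_lt(mean(errs), 2)
  # deterministic
  tr2 <- filter_min_length(track_cells(s$stack, max_link_dist = 25), 20L)
  expect_identical(tr, tr2)
})

test_that("empty stacks give an empty track list", {
  st <- toy_stack(list(matrix(numeric(0), 0, 2)), nf = 3L)
  st$data[] <- 0L
  expect_length(track_cells(st), 0)
})

test_that("filter_min_length keeps exactly the long-enough tracks", {
  mk <- function(n) list(cell_id = n, points = data.frame(frame = seq_len(n) - 1,
                                                          x = 0, y = 0),
                         label = NA_character_)
  tracks <- lapply(c(10, 19, 20, 45), mk)
  kept <- filter_min_length(tracks, 20L)
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(t) nrow(t$points), 0L), c(20L, 45L))
  expect_identical(filter_min_length(tracks, 1L), tracks)
  expect_length(filter_min_length(list(), 20L), 0)
})

test_that("track CSVs round-trip and enforce the TrackMate schema", {
  tracks <- list(
    list(cell_id = 1L, points = data.frame(frame = 0:2, x = c(1.5, 2.5, 3.25),
                                           y = c(9, 8.5, 8)), label = NA_character_),
    list(cell_id = 2L, points = data.frame(frame = 0:1, x = c(50, 51),
                                           y = c(60, 59.5)), label = NA_character_))
  tf <- tempfile(fileext = ".csv")
  write_tracks_csv(tracks, tf)
  rt <- read_tracks_csv(tf)
  expect_equal(rt, tracks, tolerance = 1e-12)
  # missing required column
  df <- read.csv(tf)
  df$POSITION_Y <- NULL
  tf2 <- tempfile(fileext = ".csv")
  write.csv(df, tf2, row.names = FALSE)
  expect_error(read_tracks_csv(tf2), "POSITION_Y",
               class = "cognatevid_schema_error")
})

test_that("real-style TrackMate export parses, extra columns dropped", {
  fx <- system.file("extdata", "trackmate_spots_synthetic.csv",
                    package = "cognatevid")
  tr <- read_tracks_csv(fx)
  expect_length(tr, 2)
  expect_equal(tr[[1]]$points$x, c(120.25, 122.10, 124.80))
  expect_equal(nrow(tr[[2]]$points), 4)
  expect_identical(tr[[2]]$points$frame, 0:3)
  expect_null(tr[[1]]$points$QUALITY)
})
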