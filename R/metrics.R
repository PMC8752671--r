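# Classical per-cell interaction metrics: overlapped pixels, red (DC) pixels,
# speed, circularity and interaction time, averaged over the frames of a
# binarized per-cell video.

#' Overlapped pixels in one binary frame
#'
#' Pixels foreground in both the DC (red) and T cell (green) channels; a proxy
#' for T cell-DC contact area.
#'
#' @param frame Binary array `(H, W, >= 2)`; channel 1 = DC, channel 2 = T cell
#'   (R 1-based slice indices).
#' @return Integer pixel count.
#' @export
overlap_pixels <- function(frame) {
  sum(as.integer(frame[, , 1]) == 1L & as.integer(frame[, , 2]) == 1L)
}

#' Red (DC) pixels in one binary frame
#'
#' @inheritParams overlap_pixels
#' @return Integer pixel count of DC-channel foreground.
#' @export
red_pixels <- function(frame) {
  sum(as.integer(frame[, , 1]) == 1L)
}

#' Mean track speed
#'
#' Mean over consecutive track links of Euclidean displacement converted to
#' micrometres per minute.
#'
#' @param track Track list with a `points` data frame (`frame`, `x`, `y`).
#' @param frame_interval Minutes between consecutive frames.
#' @param pixel_size Micrometres per pixel.
#' @return Speed in um/min.
#' @export
mean_speed <- function(track, frame_interval, pixel_size) {
  pts <- track$points
  if (nrow(pts) < 2) {
    stop_cv("speed undefined for a single-point track", "cognatevid_metric_error")
  }
  dx <- diff(pts$x); dy <- diff(pts$y); df <- diff(pts$frame)
  mean(sqrt(dx^2 + dy^2) * pixel_size / (df * frame_interval))
}

# Trace the crack (inter-pixel) boundary of the connected foreground component
# containing the raster-first pixel of `mask`. Vertices are pixel-corner
# coordinates (row, col), 0-based, closed polygon, foreground kept on the
# right of the travel direction.
crack_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- function(i, j) i >= 1 && i <= H && j >= 1 && j <= W && mask[i, j]
  start <- which(t(mask), arr.ind = FALSE)[1]   # row-major first
  sr <- (start - 1) %/% W + 1; sc <- (start - 1) %% W + 1
  # start at the top-left corner of that pixel, heading east
  verts <- matrix(NA_real_, 4 * (H * W) + 8, 2)
  r <- sr - 1; k <- sc - 1; dir <- 0L  # 0=E,1=S,2=W,3=N (corner lattice, 0-based)
  r0 <- r; k0 <- k; d0 <- dir
  nv <- 0L
  repeat {
    nv <- nv + 1L
    verts[nv, ] <- c(r, k)
    # advance one unit in direction dir
    if (dir == 0L) k <- k + 1 else if (dir == 1L) r <- r + 1
    else if (dir == 2L) k <- k - 1 else r <- r - 1
    # pixels around the new corner (1-based): NW (r, k), NE (r, k+1),
    # SW (r+1, k), SE (r+1, k+1)
    nw <- fg(r, k); ne <- fg(r, k + 1); sw <- fg(r + 1, k); se <- fg(r + 1, k + 1)
    # with fg on the right, pick next direction by right-hand wall following
    if (dir == 0L) {        # east: right-front = SE, left-front = NE
      dir <- if (se && !ne) 0L else if (!se) 1L else 3L
    } else if (dir == 1L) { # south: right-front = SW, left-front = SE
      dir <- if (sw && !se) 1L else if (!sw) 2L else 0L
    } else if (dir == 2L) { # west: right-front = NW, left-front = SW
      dir <- if (nw && !sw) 2L else if (!nw) 3L else 1L
    } else {                # north: right-front = NE, left-front = NW
      dir <- if (ne && !nw) 3L else if (!ne) 0L else 2L
    }
    if (r == r0 && k == k0 && dir == d0) break
    if (nv > 4 * H * W) stop("boundary tracing failed to close")  # nocov
  }
  verts[seq_len(nv), , drop = FALSE]
}

# Perimeter of a closed polygon after 3-point moving-average smoothing of its
# vertices. Smoothing preserves straight runs, trims digitization staircases
# toward their diagonals, and slightly cuts sharp corners, giving a perimeter
# estimate close to the underlying continuous outline (Fiji-like).
smoothed_perimeter <- function(verts) {
  n <- nrow(verts)
  if (n < 3) return(0)
  prev <- verts[c(n, seq_len(n - 1)), , drop = FALSE]
  nxt <- verts[c(seq_len(n)[-1], 1), , drop = FALSE]
  sm <- (prev + verts + nxt) / 3
  d <- sm[c(seq_len(n)[-1], 1), , drop = FALSE] - sm
  sum(sqrt(rowSums(d^2)))
}

#' Circularity of a binary mask
#'
#' `4 * pi * Area / Perimeter^2` with Area the foreground pixel count and
#' Perimeter the smoothed crack-boundary outline length of the largest
#' connected component; capped at 1. A disk scores near 1, elongated or
#' flattened shapes lower.
#'
#' @param mask Logical or 0/1 matrix with at least one foreground pixel.
#' @return Circularity in (0, 1].
#' @export
circularity <- function(mask) {
  m <- matrix(as.logical(mask), nrow(mask))
  if (!any(m)) stop_cv("empty mask has no circularity", "cognatevid_metric_error")
  lab <- .cpp_label_components(matrix(as.integer(m), nrow(m)))
  K <- max(lab)
  if (K > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = K)
    keep <- which.max(sizes)
    m <- lab == keep
  }
  area <- sum(m)
  per <- smoothed_perimeter(crack_boundary(m))
  if (per <= 0) return(1)
  min(1, 4 * pi * area / per^2)
}

#' Interaction time as a percentage of frames
#'
#' Fraction of frames in which the T cell overlaps a DC (any overlapped
#' pixels), expressed in percent.
#'
#' @param overlap_series Per-frame overlapped-pixel counts.
#' @return Percentage in \[0, 100\].
#' @export
interaction_pct <- function(overlap_series) {
  stopifnot(length(overlap_series) >= 1)
  100 * mean(overlap_series > 0)
}

# Contiguous overlap episodes (runs of frames with overlap > 0); reported for
# inspection, does not enter interaction_pct.
overlap_episodes <- function(overlap_series) {
  r <- rle(overlap_series > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start_frame = starts[r$values] - 1L,
             end_frame = ends[r$values] - 1L)
}

#' Per-cell metric summary
#'
#' Averages the five classical metrics over the frames of a binarized per-cell
#' video; speed is computed from the track restricted to the video's sampled
#' frames so the metric and the video describe the same time window.
#'
#' @param cv A [cell_video()].
#' @param track The matching track.
#' @param frame_interval Minutes per frame of the source stack.
#' @param pixel_size Micrometres per pixel.
#' @param with_circularity Compute per-frame circularity (set `FALSE` to skip
#'   the boundary tracing when the metric is not needed).
#' @return One-row data frame (`cell_id`, `mean_red_px`, `mean_overlap_px`,
#'   `mean_speed`, `mean_circularity`, `interaction_pct`, `label`).
#' @export
summarize_cell <- function(cv, track, frame_interval, pixel_size,
                           with_circularity = TRUE) {
  dat <- video_numeric(cv)
  Tn <- dim(dat)[1]
  red <- numeric(Tn); ov <- numeric(Tn); circ <- rep(NA_real_, Tn)
  for (f in seq_len(Tn)) {
    fr <- dat[f, , , ]
    red[f] <- red_pixels(fr)
    ov[f] <- overlap_pixels(fr)
    if (with_circularity && any(fr[, , 2] == 1)) circ[f] <- circularity(fr[, , 2])
  }
  src <- cv$provenance$source_frames
  sub <- track$points[track$points$frame %in% src, , drop = FALSE]
  spd <- if (nrow(sub) >= 2) {
    mean_speed(list(points = sub), frame_interval, pixel_size)
  } else NA_real_
  data.frame(cell_id = cv$cell_id,
             mean_red_px = mean(red),
             mean_overlap_px = mean(ov),
             mean_speed = spd,
             mean_circularity = if (all(is.na(circ))) NA_real_
                                else mean(circ, na.rm = TRUE),
             interaction_pct = interaction_pct(ov),
             label = cv$label,
             stringsAsFactors = FALSE)
}

#' Metric summaries for a set of cells
#'
#' @param cell_videos List of [cell_video()] objects.
#' @param tracks List of matching tracks (same order).
#' @param frame_interval,pixel_size As in [summarize_cell()].
#' @return Data frame with one row per cell.
#' @export
summarize_cells <- function(cell_videos, tracks, frame_interval, pixel_size) {
  do.call(rbind, Map(function(cv, tr) {
    summarize_cell(cv, tr, frame_interval, pixel_size)
  }, cell_videos, tracks))
}
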