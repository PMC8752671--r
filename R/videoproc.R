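# Per-cell video pipeline: moving 101x101 crop around the tracked T cell,
# neighbour masking, Gaussian blur + Huang/Otsu binarization, frame sampling.

#' Pipeline parameters for per-cell video generation
#'
#' @param crop_px Side of the square crop window in px (odd), default 101.
#' @param target_frames Number of frames in a uniformly sampled video.
#' @param blur_sigma Gaussian blur sigma in px applied before thresholding.
#' @param sampling_mode `"uniform"` (stride rule, always 20 frames) or
#'   `"consecutive"` (first `consecutive_k` frames).
#' @param consecutive_k Frame count for consecutive sampling (2, 5, 10 or 20).
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(crop_px = 101L, target_frames = 20L,
                            blur_sigma = 1.0,
                            sampling_mode = c("uniform", "consecutive"),
                            consecutive_k = 20L) {
  sampling_mode <- match.arg(sampling_mode)
  stopifnot(is_count(crop_px), crop_px %% 2 == 1, is_count(target_frames),
            blur_sigma >= 0, is_count(consecutive_k))
  structure(list(crop_px = as.integer(crop_px),
                 target_frames = as.integer(target_frames),
                 blur_sigma = blur_sigma,
                 sampling_mode = sampling_mode,
                 consecutive_k = as.integer(consecutive_k)),
            class = "pipeline_params")
}

#' Crop window around a centroid, clamped to the field
#'
#' Returns the `crop_px` x `crop_px` window centred on the rounded centroid;
#' when the centred window would cross a field border it is shifted to lie
#' fully inside, so the cell sits off-centre near the frame edge. Indices are
#' 0-based half-open `[lo, hi)`.
#'
#' @param centroid Numeric `(x, y)` with x = column, y = row (0-based px).
#' @param field_shape Integer `(H, W)` of the field.
#' @param crop_px Window side in px (odd).
#' @return List with `row_lo`, `row_hi`, `col_lo`, `col_hi`.
#' @export
crop_window <- function(centroid, field_shape, crop_px = 101L) {
  H <- field_shape[[1]]; W <- field_shape[[2]]
  if (H < crop_px || W < crop_px) {
    stop_cv(sprintf("field (%d x %d) smaller than crop window %d px",
                    H, W, crop_px), "cognatevid_sizing_error")
  }
  x <- centroid[[1]]; y <- centroid[[2]]
  if (x < 0 || x > W - 1 || y < 0 || y > H - 1) {
    stop_cv("centroid outside field", "cognatevid_sizing_error")
  }
  half <- (crop_px - 1L) %/% 2L
  rc <- floor(y + 0.5)   # nearest integer, ties toward larger index
  cc <- floor(x + 0.5)
  row_lo <- min(max(rc - half, 0), H - crop_px)
  col_lo <- min(max(cc - half, 0), W - crop_px)
  list(row_lo = as.integer(row_lo), row_hi = as.integer(row_lo + crop_px),
       col_lo = as.integer(col_lo), col_hi = as.integer(col_lo + crop_px))
}

#' Frame sampling rule
#'
#' Uniform mode reduces a video to exactly 20 frames: the first 20 frames for
#' 20-39 available frames, every other frame for 40-59, every third frame for
#' 60 or more (always anchored at frame 0, first 20 of the strided sequence).
#' Consecutive mode returns the first `k` frames.
#'
#' @param n_available Number of source frames.
#' @param mode `"uniform"` or `"consecutive"`.
#' @param k Frame count for consecutive mode.
#' @return Strictly increasing 0-based source frame indices.
#' @export
sample_frames <- function(n_available, mode = c("uniform", "consecutive"),
                          k = 20L) {
  mode <- match.arg(mode)
  n <- as.integer(n_available)
  if (mode == "uniform") {
    if (n < 20L) {
      stop_cv(sprintf("video has %d frames; fewer than 20 frames are excluded", n),
              "cognatevid_exclusion_error")
    }
    stride <- if (n < 40L) 1L else if (n < 60L) 2L else 3L
    return(seq(0L, by = stride, length.out = 20L))
  }
  if (n < k) {
    stop_cv(sprintf("video has %d frames; consecutive sampling needs %d", n, k),
            "cognatevid_exclusion_error")
  }
  seq(0L, k - 1L)
}

#' Otsu threshold of a 256-bin histogram
#'
#' Maximizes between-class variance over all cut levels `t` (classes
#' `value <= t` vs `value > t`); the smallest maximizing level is returned.
#'
#' @param hist Integer vector of 256 bin counts (bin i = intensity i - 1).
#' @return Threshold level in 0..255; foreground is `value > t`.
#' @export
otsu_threshold <- function(hist) {
  stopifnot(length(hist) == 256)
  h <- as.numeric(hist)
  n <- sum(h)
  if (n <= 0) stop_cv("empty histogram", "cognatevid_threshold_error")
  lev <- 0:255
  if (sum(h > 0) == 1) return(lev[h > 0])   # degenerate: single populated bin
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mu_tot <- m0[256] / n
  tt <- 1:255                     # cut after bin index tt (t = tt - 1 level)
  w0t <- w0[tt]; w1t <- n - w0t
  valid <- w0t > 0 & w1t > 0
  mu0 <- m0[tt] / pmax(w0t, 1)
  mu1 <- (m0[256] - m0[tt]) / pmax(w1t, 1)
  bcv <- ifelse(valid, w0t * w1t * (mu0 - mu1)^2, -Inf)
  # plateau of tied maxima (flat valley between separated modes): midpoint
  mx <- max(bcv)
  ties <- tt[bcv >= mx - 1e-10 * max(mx, 1)] - 1L
  as.integer(floor(mean(ties)))
}

#' Huang fuzzy-entropy threshold of a 256-bin histogram
#'
#' Minimizes the Huang-Wang fuzzy entropy (Shannon form) with memberships
#' based on distance to the two class means; equivalent to an exhaustive scan
#' over all 256 cut levels.
#'
#' @inheritParams otsu_threshold
#' @return Threshold level in 0..255; foreground is `value > t`.
#' @export
huang_threshold <- function(hist) {
  stopifnot(length(hist) == 256)
  h <- as.numeric(hist)
  if (sum(h) <= 0) stop_cv("empty histogram", "cognatevid_threshold_error")
  lev <- 0:255
  pop <- which(h > 0)
  if (length(pop) == 1) return(lev[pop])    # degenerate: all background
  gmin <- lev[pop[1]]; gmax <- lev[pop[length(pop)]]
  C <- gmax - gmin
  w <- cumsum(h)
  m <- cumsum(h * lev)
  n <- w[256]
  hf <- function(u) {
    # Shannon fuzzy entropy; u in [0.5, 1], define 0*log 0 = 0
    v <- -u * log(u) - (1 - u) * log1p(-u)
    v[!is.finite(v)] <- 0
    v
  }
  ent <- rep(Inf, 255)
  for (tt in 1:255) {                        # cut level t = tt - 1
    w0 <- w[tt]; w1 <- n - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- m[tt] / w0
    mu1 <- (m[256] - m[tt]) / w1
    u0 <- 1 / (1 + abs(lev[1:tt] - mu0) / C)
    u1 <- 1 / (1 + abs(lev[(tt + 1):256] - mu1) / C)
    ent[tt] <- sum(h[1:tt] * hf(u0)) + sum(h[(tt + 1):256] * hf(u1))
  }
  # plateau of tied minima: midpoint (mirror-symmetric for symmetric inputs)
  mn <- min(ent)
  ties <- which(ent <= mn + 1e-10 * max(abs(mn), 1)) - 1L
  as.integer(floor(mean(ties)))
}

# Field-level DC (red channel) threshold: Huang on the blurred, uncropped DC
# channel pooled over all frames. One scalar per field, shared by every cell
# video cut from that field.
#' Field-level Huang threshold of the DC channel
#'
#' @param stack An [ImageStack][simulate_field].
#' @param blur_sigma Gaussian blur sigma in px.
#' @return Threshold level (0..255); DC foreground is `blurred value > t`.
#' @export
field_dc_threshold <- function(stack, blur_sigma = 1.0) {
  nf <- dim(stack$data)[1]
  counts <- integer(256)
  for (f in seq_len(nf)) {
    bl <- gaussian_blur(stack$data[f, , , 1], blur_sigma)
    counts <- counts + intensity_hist(bl)
  }
  if (sum(counts[-1]) == 0 && all(stack$data[, , , 1] == stack$data[1, 1, 1, 1])) {
    warning("constant DC channel: threshold set to +Inf (all-background)",
            call. = FALSE)
    return(Inf)
  }
  huang_threshold(counts)
}

# Binary dilation of a logical matrix by a disk of radius r (px).
dilate_disk <- function(mask, r) {
  if (r <= 0 || !any(mask)) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= r^2, ]
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, H, W)
  for (k in seq_len(nrow(off))) {
    ii <- idx[, 1] + off$di[k]; jj <- idx[, 2] + off$dj[k]
    keep <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    out[cbind(ii[keep], jj[keep])] <- TRUE
  }
  out
}

#' Mask neighbouring T cells out of a cropped video
#'
#' Sets channel-1 (T cell) pixels outside the per-frame ROI of the tracked
#' cell to zero; the DC channel is untouched.
#'
#' @param cropped Numeric array `(T, crop, crop, 3)`.
#' @param rois List of logical `crop x crop` matrices, one per frame.
#' @return The masked array.
#' @export
mask_neighbors <- function(cropped, rois) {
  stopifnot(length(rois) == dim(cropped)[1])
  for (f in seq_along(rois)) {
    roi <- rois[[f]]
    if (!any(roi)) {
      warning(sprintf("empty ROI in frame %d: T-cell channel zeroed", f),
              call. = FALSE)
      cropped[f, , , 2] <- 0
    } else {
      fr <- cropped[f, , , 2]
      fr[!roi] <- 0
      cropped[f, , , 2] <- fr
    }
  }
  cropped
}

# ROI of the tracked cell in a cropped frame: connected component of the
# provisionally binarized T-cell channel nearest to the (local) track
# centroid, dilated by 2 px. Returns a logical matrix (possibly all-FALSE).
tcell_roi <- function(bin_ch1, centroid_local, dilate = 2L) {
  lab <- .cpp_label_components(matrix(as.integer(bin_ch1), nrow(bin_ch1)))
  K <- max(lab)
  if (K == 0) return(matrix(FALSE, nrow(bin_ch1), ncol(bin_ch1)))
  # nearest component: min distance from any of its pixels to the centroid
  cx <- centroid_local[[1]]; cy <- centroid_local[[2]]
  best <- 1L; bestd <- Inf
  for (k in seq_len(K)) {
    px <- which(lab == k, arr.ind = TRUE)
    d <- min((px[, 1] - 1 - cy)^2 + (px[, 2] - 1 - cx)^2)
    if (d < bestd) { bestd <- d; best <- k }
  }
  dilate_disk(lab == best, dilate)
}

#' Blur and binarize a cropped two-channel video
#'
#' Both channels are Gaussian-blurred, then thresholded to \{0, 1\}: the DC
#' channel against the field-level Huang threshold (computed on the uncropped
#' field) and the T-cell channel against an Otsu threshold computed once per
#' cell video on the pooled post-crop histogram.
#'
#' @param cropped Numeric array `(T, crop, crop, 3)` (masked).
#' @param dc_threshold Field-level DC threshold from [field_dc_threshold()].
#' @param blur_sigma Gaussian blur sigma in px.
#' @param channels Channels to process (1 = DC, 2 = T cell); others stay zero.
#' @return Integer \{0, 1\} array of the same shape (channel 2 all zero).
#' @export
binarize <- function(cropped, dc_threshold, blur_sigma = 1.0,
                     channels = c(1L, 2L)) {
  nf <- dim(cropped)[1]
  out <- array(0L, dim = dim(cropped))
  blurred_g <- vector("list", nf)
  if (2L %in% channels) {
    counts <- integer(256)
    for (f in seq_len(nf)) {
      blurred_g[[f]] <- gaussian_blur(cropped[f, , , 2], blur_sigma)
      counts <- counts + intensity_hist(blurred_g[[f]])
    }
    g_thr <- if (sum(counts[-1]) == 0) {
      if (counts[1] == sum(counts)) {
        warning("constant T-cell channel: threshold set to +Inf", call. = FALSE)
      }
      Inf
    } else otsu_threshold(counts)
    for (f in seq_len(nf)) {
      out[f, , , 2] <- as.integer(floor(pmin(pmax(blurred_g[[f]], 0), 255)) > g_thr)
    }
  }
  if (1L %in% channels) {
    for (f in seq_len(nf)) {
      bl_r <- gaussian_blur(cropped[f, , , 1], blur_sigma)
      out[f, , , 1] <- as.integer(floor(pmin(pmax(bl_r, 0), 255)) > dc_threshold)
    }
  }
  out
}

#' Build the per-cell classifier input video
#'
#' Runs the full per-cell pipeline: frame sampling, moving crop around the
#' track centroid, neighbour masking (ROI = provisionally binarized component
#' nearest the centroid, dilated 2 px), Gaussian blur and Huang/Otsu
#' binarization.
#'
#' @param stack An [ImageStack][simulate_field].
#' @param track A track (list with `cell_id`, `points`, optional `label`).
#' @param pp A [pipeline_params()] object.
#' @param dc_threshold Optional precomputed [field_dc_threshold()]; computed
#'   from `stack` when `NULL`.
#' @return A `cell_video` object: binary array `data` of dim
#'   `(frames, crop, crop, 3)` stored as raw, plus `cell_id`, `label` and
#'   `provenance` (sampling mode and 0-based source frame indices).
#' @export
cell_video <- function(stack, track, pp = pipeline_params(),
                       dc_threshold = NULL) {
  pts <- track$points
  n_avail <- nrow(pts)
  sel0 <- sample_frames(n_avail,
                        mode = pp$sampling_mode,
                        k = pp$consecutive_k)
  .cell_video_at(stack, track, pp, sel0, dc_threshold)
}

# Core pipeline for an explicit set of 0-based point indices `sel0` into the
# track. Used by cell_video() and the dataset builder (which processes all
# frames once and slices afterwards).
.cell_video_at <- function(stack, track, pp, sel0, dc_threshold = NULL) {
  if (is.null(dc_threshold)) dc_threshold <- field_dc_threshold(stack, pp$blur_sigma)
  pts <- track$points
  H <- dim(stack$data)[2]; W <- dim(stack$data)[3]
  sel <- sel0 + 1L
  Tn <- length(sel)
  crop <- pp$crop_px
  cropped <- array(0, dim = c(Tn, crop, crop, 3))
  centers <- matrix(0, Tn, 2)     # local (x, y) of the track centroid
  for (i in seq_len(Tn)) {
    p <- pts[sel[i], ]
    win <- crop_window(c(p$x, p$y), c(H, W), crop)
    fr <- stack$data[p$frame + 1L, (win$row_lo + 1L):win$row_hi,
                     (win$col_lo + 1L):win$col_hi, ]
    cropped[i, , , ] <- fr
    centers[i, ] <- c(p$x - win$col_lo, p$y - win$row_lo)
  }
  # provisional binarization of the T-cell channel to derive per-frame ROIs
  prov <- binarize(cropped, dc_threshold, pp$blur_sigma, channels = 2L)
  rois <- lapply(seq_len(Tn), function(i) {
    tcell_roi(prov[i, , , 2] == 1L, centers[i, ])
  })
  masked <- mask_neighbors(cropped, rois)
  bin <- binarize(masked, dc_threshold, pp$blur_sigma)
  data <- array(as.raw(bin), dim = dim(bin))
  structure(list(data = data,
                 cell_id = track$cell_id,
                 label = track$label %||% NA_character_,
                 provenance = list(sampling_mode = pp$sampling_mode,
                                   source_frames = pts$frame[sel],
                                   crop_px = crop,
                                   blur_sigma = pp$blur_sigma,
                                   dc_threshold = dc_threshold)),
            class = "cell_video")
}

#' @export
print.cell_video <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cell_video> cell %s (%s): %d frames of %dx%d, sampling=%s\n",
              x$cell_id, x$label, d[1], d[2], d[3],
              x$provenance$sampling_mode))
  invisible(x)
}

# Slice a processed cell video to a subset of its frames (0-based indices into
# the stored frames), relabelling provenance. Internal.
subset_cell_video <- function(cv, idx0, mode) {
  idx <- idx0 + 1L
  data <- cv$data[idx, , , , drop = FALSE]
  out <- cv
  out$data <- array(data, dim = c(length(idx), dim(cv$data)[2:4]))
  out$provenance$sampling_mode <- mode
  out$provenance$source_frames <- cv$provenance$source_frames[idx]
  out
}

# Numeric (double) view of a cell video's binary data.
video_numeric <- function(cv) {
  array(as.integer(cv$data), dim = dim(cv$data))
}

#' Spatially downsample a cell video
#'
#' Keeps every `factor`-th pixel along both spatial axes (e.g. 101 px to
#' 51 px at factor 2). Used to scale the classifier benchmarks down to
#' desk-scale CPU budgets; the published input size is the default elsewhere.
#'
#' @param cv A [cell_video()].
#' @param factor Integer subsampling factor.
#' @return The downsampled `cell_video`.
#' @export
downsample_video <- function(cv, factor = 2L) {
  stopifnot(is_count(factor))
  if (factor == 1L) return(cv)
  idx <- seq(1L, dim(cv$data)[2], by = factor)
  cv$data <- cv$data[, idx, idx, , drop = FALSE]
  cv$provenance$downsample <- as.integer(factor)
  cv
}
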