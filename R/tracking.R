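# Per-cell tracks: greedy mutual nearest-neighbour tracker over channel-1
# connected-component centroids, plus TrackMate-style CSV interoperability.
#
# Coordinate convention (used everywhere): 0-based, x = column, y = row,
# origin top-left; positions are intensity-weighted centroids.

# Detect T cells in one frame: blur, per-frame Otsu, 8-connected components,
# intensity-weighted centroids. Components below min_area px are discarded as
# noise specks.
detect_frame <- function(frame_ch1, blur_sigma = 1.0, min_area = 9L) {
  bl <- gaussian_blur(frame_ch1, blur_sigma)
  counts <- intensity_hist(bl)
  if (sum(counts[-1]) == 0) return(matrix(numeric(0), 0, 2))
  thr <- otsu_threshold(counts)
  bin <- matrix(as.integer(floor(pmin(pmax(bl, 0), 255)) > thr), nrow(bl))
  lab <- .cpp_label_components(bin)
  K <- max(lab)
  if (K == 0) return(matrix(numeric(0), 0, 2))
  cent <- matrix(NA_real_, K, 2)
  keep <- logical(K)
  for (k in seq_len(K)) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) < min_area) next
    w <- bl[px]
    keep[k] <- TRUE
    cent[k, ] <- c(sum((px[, 2] - 1) * w) / sum(w),   # x
                   sum((px[, 1] - 1) * w) / sum(w))   # y
  }
  cent[keep, , drop = FALSE]
}

#' Track T cells through an image stack
#'
#' Greedy mutual nearest-neighbour linking of per-frame channel-1 connected
#' component centroids: the globally closest (track end, detection) pair
#' within `max_link_dist` is linked first, ties broken by smaller track id;
#' unlinked detections start new tracks and gaps are not closed (a missed
#' detection ends the track).
#'
#' @param stack An `image_stack` with at least two frames.
#' @param max_link_dist Maximum per-frame link distance in px.
#' @param blur_sigma Detection blur sigma.
#' @param min_area Minimum detected component area in px.
#' @return List of tracks (each a list with `cell_id`, `points`, `label = NA`);
#'   empty when no cells are ever detected.
#' @export
track_cells <- function(stack, max_link_dist = 20, blur_sigma = 1.0,
                        min_area = 9L) {
  nf <- dim(stack$data)[1]
  if (nf < 2) stop_cv("tracking needs at least 2 frames", "cognatevid_track_error")
  tracks <- list()        # each: list(points = data.frame, open = TRUE)
  open_idx <- integer(0)  # indices of tracks extendable into the next frame
  for (f in seq_len(nf)) {
    det <- detect_frame(stack$data[f, , , 2], blur_sigma, min_area)
    nd <- nrow(det)
    linked_det <- rep(FALSE, nd)
    still_open <- integer(0)
    if (length(open_idx) && nd) {
      ends <- do.call(rbind, lapply(tracks[open_idx], function(t) {
        unlist(t$points[nrow(t$points), c("x", "y")])
      }))
      D <- outer(ends[, 1], det[, 1], "-")^2 + outer(ends[, 2], det[, 2], "-")^2
      used_tr <- rep(FALSE, length(open_idx))
      repeat {
        D2 <- D
        D2[used_tr, ] <- Inf
        D2[, linked_det] <- Inf
        m <- min(D2)
        if (!is.finite(m) || m > max_link_dist^2) break
        hit <- which(D2 == m, arr.ind = TRUE)
        hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]  # tie-break
        ti <- open_idx[hit[1]]
        tracks[[ti]]$points <- rbind(tracks[[ti]]$points,
                                     data.frame(frame = f - 1L,
                                                x = det[hit[2], 1],
                                                y = det[hit[2], 2]))
        used_tr[hit[1]] <- TRUE
        linked_det[hit[2]] <- TRUE
        still_open <- c(still_open, ti)
      }
    }
    if (nd) {
      for (d in which(!linked_det)) {
        tracks[[length(tracks) + 1L]] <-
          list(points = data.frame(frame = f - 1L, x = det[d, 1], y = det[d, 2]))
        still_open <- c(still_open, length(tracks))
      }
    }
    open_idx <- still_open
  }
  lapply(seq_along(tracks), function(i) {
    list(cell_id = i, points = tracks[[i]]$points, label = NA_character_)
  })
}

#' Drop tracks shorter than a minimum frame count
#'
#' Cells followed for fewer than `min_frames` frames are excluded (default 20,
#' the minimum video length accepted by the classifier pipeline).
#'
#' @param tracks List of tracks.
#' @param min_frames Minimum number of track points.
#' @return The surviving tracks, order preserved.
#' @export
filter_min_length <- function(tracks, min_frames = 20L) {
  stopifnot(is_count(min_frames))
  tracks[vapply(tracks, function(t) nrow(t$points) >= min_frames, TRUE)]
}

#' TrackMate-compatible track CSV import/export
#'
#' Reads spot tables with columns `TRACK_ID`, `FRAME`, `POSITION_X`,
#' `POSITION_Y` (extra columns are ignored); positions are parsed as floating
#' pixel coordinates. `write_tracks_csv` writes the same four columns.
#'
#' @param path CSV file path.
#' @param tracks List of tracks.
#' @return `read_tracks_csv` returns a list of tracks sorted by frame.
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path, check.names = TRUE)
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_cv(paste0("track CSV missing required column(s): ",
                   paste(missing, collapse = ", ")),
            "cognatevid_schema_error")
  }
  # TrackMate exports carry up to three repeated header rows; drop non-numeric
  suppressWarnings({
    num <- !is.na(as.numeric(as.character(df$FRAME)))
  })
  df <- df[num, , drop = FALSE]
  df$TRACK_ID <- as.numeric(as.character(df$TRACK_ID))
  df$FRAME <- as.numeric(as.character(df$FRAME))
  df$POSITION_X <- as.numeric(as.character(df$POSITION_X))
  df$POSITION_Y <- as.numeric(as.character(df$POSITION_Y))
  out <- lapply(split(df, df$TRACK_ID), function(d) {
    d <- d[order(d$FRAME), ]
    list(cell_id = as.integer(d$TRACK_ID[1]),
         points = data.frame(frame = as.integer(d$FRAME),
                             x = d$POSITION_X, y = d$POSITION_Y),
         label = NA_character_)
  })
  names(out) <- NULL
  out
}

#' @rdname read_tracks_csv
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(t) {
    data.frame(TRACK_ID = t$cell_id, FRAME = t$points$frame,
               POSITION_X = t$points$x, POSITION_Y = t$points$y)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
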