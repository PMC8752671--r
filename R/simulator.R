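# Agent-based simulator of two-channel T cell-DC interaction videos with
# ground-truth tracks, labels and contact intervals.
#
# Motility is a persistent random walk (heading perturbed each step); DCs are
# slow persistent walkers; contact begins when the centre distance drops below
# capture_radius, lasts an exponential dwell, and ends with a repulsive kick
# plus a short refractory period so transient scanning is visually distinct.
# Walls reflect. Cells render as anti-aliased ellipses at intensity 200.

# Ellipse aspect ratio (b/a) matching a target circularity, using the
# Ramanujan perimeter approximation. Memoized.
.aspect_cache <- new.env(parent = emptyenv())
ellipse_aspect <- function(circ) {
  key <- sprintf("%.5f", circ)
  if (!is.null(.aspect_cache[[key]])) return(.aspect_cache[[key]])
  f <- function(q) {
    P <- pi * (3 * (1 + q) - sqrt((3 + q) * (1 + 3 * q)))
    4 * pi * (pi * q) / P^2 - circ
  }
  q <- if (circ >= 1) 1 else uniroot(f, c(1e-4, 1), tol = 1e-8)$root
  .aspect_cache[[key]] <- q
  q
}

reflect1 <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x else x <- 2 * hi - x
  }
  x
}

# DC trajectories: matrix (n_frames, 2) per DC, list over DCs. Each DC has its
# own derived stream, so adding DCs never reshuffles existing ones.
simulate_dc_paths <- function(p) {
  H <- p$field_px
  paths <- vector("list", p$n_dcs)
  margin <- p$dc_radius
  step_px <- p$speed_dc * p$frame_interval / p$pixel_size
  sd_turn <- (1 - p$persistence) * pi
  for (j in seq_len(p$n_dcs)) {
    with_seed(seed_child(p$seed, c(1L, j)), function() {
      pos <- NULL
      for (att in 1:5000) {
        cand <- runif(2, margin, H - 1 - margin)
        ok <- TRUE
        for (jj in seq_len(j - 1)) {
          if (sum((cand - paths[[jj]][1, ])^2) < (2 * p$dc_radius)^2) ok <- FALSE
        }
        if (ok) { pos <- cand; break }
      }
      if (is.null(pos)) {
        stop_cv("field too small to place DCs without overlap",
                "cognatevid_sizing_error")
      }
      phi <- runif(1, 0, 2 * pi)
      turns <- rnorm(p$n_frames, 0, sd_turn)
      path <- matrix(0, p$n_frames, 2)
      path[1, ] <- pos
      for (f in 2:p$n_frames) {
        phi <- phi + turns[f]
        pos <- path[f - 1, ] + step_px * c(cos(phi), sin(phi))
        pos[1] <- reflect1(pos[1], margin, H - 1 - margin)
        pos[2] <- reflect1(pos[2], margin, H - 1 - margin)
        path[f, ] <- pos
      }
      paths[[j]] <<- path
    })
  }
  paths
}

# One T cell's trajectory, contact intervals and per-frame shape, given the
# (fixed) DC paths. All randomness comes from the cell's own derived stream.
simulate_tcell <- function(p, k, dc_paths, label, acd40) {
  H <- p$field_px
  nf <- p$n_frames
  margin <- p$tcell_radius
  sd_turn <- (1 - p$persistence) * pi
  dwell_mean <- if (label == "cognate") p$dwell_mean_cognate else {
    p$dwell_mean_noncognate * (if (acd40) p$acd40_noncog_dwell_factor else 1)
  }
  gain <- if (label == "cognate" && acd40) p$acd40_overlap_gain else 1
  d_att <- (p$dc_radius + 0.4 * p$tcell_radius) / gain
  circ_target_contact <- if (label == "cognate") p$contact_circ_cognate
                         else p$contact_circ_noncognate
  out <- NULL
  with_seed(seed_child(p$seed, c(2L, k)), function() {
    speed <- max(0.5, rnorm(1, p$speed_free[["mean"]], p$speed_free[["sd"]]))
    step_px <- speed * p$frame_interval / p$pixel_size
    pos <- NULL
    placed <- attr(dc_paths, "tcell_starts") %||% list()
    for (att in 1:5000) {
      cand <- runif(2, margin, H - 1 - margin)
      ok <- TRUE
      for (q in placed) if (sum((cand - q)^2) < (2 * p$tcell_radius)^2) ok <- FALSE
      for (dp in dc_paths) {
        if (sum((cand - dp[1, ])^2) < (p$capture_radius + 2)^2) ok <- FALSE
      }
      if (ok) { pos <- cand; break }
    }
    if (is.null(pos)) {
      stop_cv("field too small to place T cells at non-overlapping start positions",
              "cognatevid_sizing_error")
    }
    phi <- runif(1, 0, 2 * pi)
    turns <- rnorm(nf, 0, sd_turn)
    wobble <- rnorm(nf, 0, 0.15)
    xy <- matrix(0, nf, 2)
    xy[1, ] <- pos
    circ <- numeric(nf)
    circ[1] <- p$free_circularity
    theta <- numeric(nf)
    theta[1] <- phi
    contact_dc <- 0L
    frames_left <- 0L
    refractory <- 0L
    rel_angle <- 0
    intervals <- list()
    cur_start <- NA_integer_
    for (f in 2:nf) {
      in_contact <- contact_dc > 0L
      if (in_contact) {
        dc <- dc_paths[[contact_dc]][f, ]
        rel_angle <- rel_angle + wobble[f]
        phi <- phi + turns[f]
        jitter <- p$arrest_speed_factor * step_px * c(cos(phi), sin(phi))
        tent <- dc + d_att * c(cos(rel_angle), sin(rel_angle)) + jitter
        u <- tent - dc
        nu <- sqrt(sum(u^2))
        if (nu < 1e-9) u <- c(1, 0) else u <- u / nu
        rel_angle <- atan2(u[2], u[1])
        pos <- dc + d_att * u
        pos[1] <- reflect1(pos[1], margin, H - 1 - margin)
        pos[2] <- reflect1(pos[2], margin, H - 1 - margin)
        frames_left <- frames_left - 1L
        if (frames_left <= 0L) {
          intervals[[length(intervals) + 1L]] <-
            c(cur_start, f - 1L, contact_dc)   # 0-based inclusive frames
          contact_dc <- 0L
          refractory <- 3L
          phi <- rel_angle        # kicked radially away from the DC
        }
      } else {
        phi <- phi + turns[f]
        pos <- xy[f - 1, ] + step_px * c(cos(phi), sin(phi))
        pos[1] <- reflect1(pos[1], margin, H - 1 - margin)
        pos[2] <- reflect1(pos[2], margin, H - 1 - margin)
        if (refractory > 0L) {
          refractory <- refractory - 1L
        } else {
          d2 <- vapply(dc_paths, function(dp) sum((pos - dp[f, ])^2), 0)
          j <- which.min(d2)
          if (length(j) && d2[j] <= p$capture_radius^2) {
            contact_dc <- j
            dwell_min <- rexp(1, 1 / dwell_mean)
            frames_left <- max(1L, as.integer(ceiling(dwell_min / p$frame_interval)))
            rel_angle <- atan2(pos[2] - dc_paths[[j]][f, 2],
                               pos[1] - dc_paths[[j]][f, 1])
            cur_start <- f - 1L
          }
        }
      }
      xy[f, ] <- pos
      target <- if (contact_dc > 0L) circ_target_contact else p$free_circularity
      circ[f] <- circ[f - 1] + 0.5 * (target - circ[f - 1])
      theta[f] <- if (contact_dc > 0L) rel_angle + pi / 2 else phi
    }
    if (contact_dc > 0L) {
      intervals[[length(intervals) + 1L]] <- c(cur_start, nf - 1L, contact_dc)
    }
    iv <- if (length(intervals)) {
      m <- do.call(rbind, intervals)
      data.frame(start_frame = m[, 1], end_frame = m[, 2], dc_id = m[, 3])
    } else {
      data.frame(start_frame = integer(0), end_frame = integer(0),
                 dc_id = integer(0))
    }
    out <<- list(xy = xy, circ = circ, theta = theta, intervals = iv)
  })
  out
}

#' Simulate a two-channel T cell-DC interaction field
#'
#' Generates an image stack (channel 0 = DC "red", channel 1 = T cell "green",
#' channel 2 empty) together with ground-truth tracks, labels and contact
#' intervals. All T cells in a field share one condition, mirroring cognate
#' (peptide-pulsed) vs non-cognate (un-pulsed) co-culture wells, with or
#' without aCD40. Identical `(params, condition, seed)` give bit-identical
#' output.
#'
#' @param params A [sim_params()] object.
#' @param label `"cognate"` or `"non-cognate"`.
#' @param acd40 Logical: apply the aCD40 effect multipliers.
#' @return List with `stack` (an `image_stack`: integer array
#'   `(n_frames, H, W, 3)` on the 0-255 scale plus metadata) and `truth`
#'   (`tracks`, `labels`, `contact_intervals`).
#' @export
simulate_field <- function(params, label = c("cognate", "non-cognate"),
                           acd40 = FALSE) {
  label <- match.arg(label)
  validate_sim_params(params)
  p <- params
  H <- p$field_px
  dc_paths <- simulate_dc_paths(p)
  cells <- vector("list", p$n_tcells)
  starts <- list()
  for (k in seq_len(p$n_tcells)) {
    attr(dc_paths, "tcell_starts") <- starts
    cells[[k]] <- simulate_tcell(p, k, dc_paths, label, acd40)
    starts[[k]] <- cells[[k]]$xy[1, ]
  }
  attr(dc_paths, "tcell_starts") <- NULL
  q_cache <- list()
  data <- array(0L, dim = c(p$n_frames, H, H, 3))
  for (f in seq_len(p$n_frames)) {
    ch0 <- matrix(0, H, H)
    ch1 <- matrix(0, H, H)
    for (dp in dc_paths) {
      .cpp_add_ellipse(ch0, dp[f, 1], dp[f, 2], p$dc_radius, p$dc_radius, 0, 200)
    }
    for (cl in cells) {
      q <- ellipse_aspect(cl$circ[f])
      a <- p$tcell_radius / sqrt(q)
      b <- p$tcell_radius * sqrt(q)
      .cpp_add_ellipse(ch1, cl$xy[f, 1], cl$xy[f, 2], a, b, cl$theta[f], 200)
    }
    if (p$noise_sd > 0) {
      with_seed(seed_child(p$seed, c(3L, f)), function() {
        ch0 <<- ch0 + rnorm(H * H, 0, p$noise_sd)
        ch1 <<- ch1 + rnorm(H * H, 0, p$noise_sd)
      })
    }
    data[f, , , 1] <- as.integer(round(pmin(pmax(ch0, 0), 255)))
    data[f, , , 2] <- as.integer(round(pmin(pmax(ch1, 0), 255)))
  }
  stack <- structure(list(data = data,
                          frame_interval = p$frame_interval,
                          pixel_size = p$pixel_size,
                          channels = c("DC", "TCELL", "EMPTY")),
                     class = "image_stack")
  tracks <- lapply(seq_len(p$n_tcells), function(k) {
    list(cell_id = k,
         points = data.frame(frame = 0:(p$n_frames - 1),
                             x = cells[[k]]$xy[, 1],
                             y = cells[[k]]$xy[, 2]),
         label = label)
  })
  truth <- list(tracks = tracks,
                labels = setNames(rep(label, p$n_tcells), seq_len(p$n_tcells)),
                condition = if (acd40) "+aCD40" else "-aCD40",
                contact_intervals = lapply(cells, `[[`, "intervals"))
  list(stack = stack, truth = truth)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frames, %dx%d px, %d channels (%s), %g min/frame, %g um/px\n",
              d[1], d[2], d[3], d[4], paste(x$channels, collapse = "/"),
              x$frame_interval, x$pixel_size))
  invisible(x)
}

#' Write/read ground-truth tracks and labels as CSV
#'
#' Tracks are written as `cell_id, frame, x, y`; labels as
#' `cell_id, label, condition`.
#'
#' @param truth The `truth` component of [simulate_field()].
#' @param tracks_path,labels_path Output CSV paths.
#' @export
write_ground_truth <- function(truth, tracks_path, labels_path) {
  tr <- do.call(rbind, lapply(truth$tracks, function(t) {
    cbind(cell_id = t$cell_id, t$points)
  }))
  write.csv(tr, tracks_path, row.names = FALSE)
  lb <- data.frame(cell_id = as.integer(names(truth$labels)),
                   label = unname(truth$labels),
                   condition = truth$condition)
  write.csv(lb, labels_path, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_ground_truth
#' @return `read_ground_truth` returns a list with `tracks` and `labels`.
#' @export
read_ground_truth <- function(tracks_path, labels_path) {
  tr <- read.csv(tracks_path)
  lb <- read.csv(labels_path)
  tracks <- lapply(split(tr, tr$cell_id), function(d) {
    d <- d[order(d$frame), ]
    list(cell_id = d$cell_id[1],
         points = data.frame(frame = d$frame, x = d$x, y = d$y),
         label = lb$label[match(d$cell_id[1], lb$cell_id)])
  })
  names(tracks) <- NULL
  list(tracks = tracks,
       labels = setNames(lb$label, lb$cell_id),
       condition = lb$condition[1])
}
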