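# Simulation parameters: the stated world of the synthetic co-culture.

#' Simulation parameters for synthetic T cell-DC interaction videos
#'
#' Defaults emulate an in vitro CD8+ T cell / bone-marrow-derived DC co-culture
#' imaged every 2 min for 90 min (45 frames): freely scanning T cells move as
#' persistent random walkers at ~6 um/min, DCs drift slowly at ~1 um/min,
#' cognate contacts draw long exponential dwell times (synapse, 30 min mean)
#' during which the T cell arrests and flattens against the DC, non-cognate
#' contacts are short (3 min mean). The aCD40 multipliers widen the
#' cognate/non-cognate separation: contact is tighter for cognate cells
#' (`acd40_overlap_gain`) and shorter for non-cognate cells
#' (`acd40_noncog_dwell_factor`).
#'
#' @param field_px Square field side in px (>= 202 so a 101 px crop fits).
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval Minutes between frames.
#' @param n_frames Number of frames.
#' @param n_tcells,n_dcs Cell counts.
#' @param tcell_radius,dc_radius Rendered cell radii in px.
#' @param speed_free Named `(mean, sd)` of per-cell free T cell speed, um/min.
#' @param speed_dc DC drift speed, um/min.
#' @param persistence Directional persistence in \[0, 1\] (1 = straight).
#' @param capture_radius Centre-to-centre contact initiation distance, px.
#' @param dwell_mean_cognate,dwell_mean_noncognate Exponential contact dwell
#'   means, minutes (cognate must exceed non-cognate).
#' @param arrest_speed_factor Multiplier in \[0, 1\] on T cell speed in contact.
#' @param contact_circ_cognate,contact_circ_noncognate Target T cell
#'   circularity while in contact (cognate lower: flattened synapse).
#' @param free_circularity Target circularity while scanning freely.
#' @param acd40_overlap_gain Multiplier >= 1 tightening cognate contacts when
#'   aCD40 is present.
#' @param acd40_noncog_dwell_factor Multiplier <= 1 on non-cognate dwell when
#'   aCD40 is present.
#' @param noise_sd Additive Gaussian intensity noise (8-bit scale).
#' @param seed Master seed; per-cell streams are derived from it.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(field_px = 320L,
                       pixel_size = 1.0,
                       frame_interval = 2.0,
                       n_frames = 45L,
                       n_tcells = 8L,
                       n_dcs = 26L,
                       tcell_radius = 5,
                       dc_radius = 9,
                       speed_free = c(mean = 6, sd = 1.5),
                       speed_dc = 1,
                       persistence = 0.7,
                       capture_radius = 16,
                       dwell_mean_cognate = 30,
                       dwell_mean_noncognate = 3,
                       arrest_speed_factor = 0.15,
                       contact_circ_cognate = 0.45,
                       contact_circ_noncognate = 0.8,
                       free_circularity = 0.85,
                       acd40_overlap_gain = 1.3,
                       acd40_noncog_dwell_factor = 0.5,
                       noise_sd = 8,
                       seed = 1L) {
  p <- list(field_px = as.integer(field_px), pixel_size = pixel_size,
            frame_interval = frame_interval, n_frames = as.integer(n_frames),
            n_tcells = as.integer(n_tcells), n_dcs = as.integer(n_dcs),
            tcell_radius = tcell_radius, dc_radius = dc_radius,
            speed_free = speed_free, speed_dc = speed_dc,
            persistence = persistence, capture_radius = capture_radius,
            dwell_mean_cognate = dwell_mean_cognate,
            dwell_mean_noncognate = dwell_mean_noncognate,
            arrest_speed_factor = arrest_speed_factor,
            contact_circ_cognate = contact_circ_cognate,
            contact_circ_noncognate = contact_circ_noncognate,
            free_circularity = free_circularity,
            acd40_overlap_gain = acd40_overlap_gain,
            acd40_noncog_dwell_factor = acd40_noncog_dwell_factor,
            noise_sd = noise_sd, seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  pos <- c("field_px", "pixel_size", "frame_interval", "n_frames",
           "tcell_radius", "dc_radius", "speed_dc", "capture_radius",
           "dwell_mean_cognate", "dwell_mean_noncognate")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || any(p[[f]] <= 0)) {
      stop_cv(sprintf("sim_params$%s must be > 0", f), "cognatevid_param_error")
    }
  }
  stopifnot(length(p$speed_free) == 2, all(p$speed_free > 0))
  if (p$field_px < 2 * 101) {
    stop_cv("field_px must be at least 202 (twice the 101 px crop)",
            "cognatevid_param_error")
  }
  if (p$dwell_mean_cognate <= p$dwell_mean_noncognate) {
    stop_cv("dwell_mean_cognate must exceed dwell_mean_noncognate",
            "cognatevid_param_error")
  }
  if (p$contact_circ_cognate >= p$contact_circ_noncognate) {
    stop_cv("contact_circ_cognate must be below contact_circ_noncognate",
            "cognatevid_param_error")
  }
  stopifnot(p$persistence >= 0, p$persistence <= 1,
            p$arrest_speed_factor >= 0, p$arrest_speed_factor <= 1,
            p$acd40_overlap_gain >= 1, p$acd40_noncog_dwell_factor <= 1,
            p$acd40_noncog_dwell_factor > 0,
            p$noise_sd >= 0)
  invisible(p)
}

#' Parameter presets for other T cell populations
#'
#' `"Q4-like"` emulates lower-affinity cognate interactions: cells stay motile
#' though slower (intermediate arrest factor) while contact dwell and overlap
#' are essentially unchanged. `"strainB"` emulates a different TCR-transgenic
#' strain with modest (+/- 20%) shifts in speed and dwell. `"separable"` is
#' the wide-parameter-gap co-culture used for classifier benchmarks: nearly
#' every cognate cell finds a DC (denser DC lawn) and engages it for most of
#' the video (60 min dwell), while non-cognate contacts are very transient
#' (1.5 min); the dynamics model is unchanged.
#'
#' @param name Preset name.
#' @param base Baseline [sim_params()] to modify.
#' @return A `sim_params` object.
#' @export
sim_params_preset <- function(name = c("Q4-like", "strainB", "separable"),
                              base = sim_params()) {
  name <- match.arg(name)
  p <- unclass(base)
  if (name == "Q4-like") {
    p$arrest_speed_factor <- 0.45   # motile, albeit slower, while engaged
  } else if (name == "strainB") {
    p$speed_free <- p$speed_free * 1.2
    p$dwell_mean_cognate <- p$dwell_mean_cognate * 0.8
    p$dwell_mean_noncognate <- p$dwell_mean_noncognate * 1.2
  } else {
    p$n_dcs <- 40L
    p$dwell_mean_cognate <- 60
    p$dwell_mean_noncognate <- 1.5
    p$arrest_speed_factor <- 0.1
  }
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

#' Read/write simulation parameters as a flat key=value config file
#'
#' @param path File path.
#' @param params A [sim_params()] object.
#' @return `read_sim_config` returns a `sim_params` object.
#' @export
write_sim_config <- function(params, path) {
  p <- unclass(params)
  lines <- unlist(lapply(names(p), function(nm) {
    v <- p[[nm]]
    if (length(v) > 1) {
      paste0(nm, "=", paste(v, collapse = ","))
    } else paste0(nm, "=", v)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  p <- list()
  for (e in kv) {
    val <- as.numeric(strsplit(e[2], ",", fixed = TRUE)[[1]])
    p[[trimws(e[1])]] <- val
  }
  if (!is.null(p$speed_free)) names(p$speed_free) <- c("mean", "sd")
  do.call(sim_params, p)
}
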