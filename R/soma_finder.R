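#' Step 2 configuration: coarse soma search at 63x
#'
#' @param threshold_factor binarization cutoff as a multiple of the mean
#'   frame intensity (empirically 8).
#' @param diameter_gate_um `(min, max)` equivalent diameter accepted as a
#'   soma, um. The 2-6 um diameter reading is adopted (consistent with ALM
#'   soma size); configurable.
#' @param min_circularity minimum `4 pi A / P^2` for a circular feature.
#' @param z_step_um coarse z-step into the worm body, um.
#' @param max_iterations frames examined before the worm is flushed.
#' @return A `soma_config` list.
#' @export
soma_config <- function(threshold_factor = 8, diameter_gate_um = c(2, 6),
                        min_circularity = 0.6, z_step_um = 2.5,
                        max_iterations = 10L) {
  stopifnot(threshold_factor > 0, diameter_gate_um[1] < diameter_gate_um[2],
            z_step_um > 0, max_iterations >= 1)
  structure(list(threshold_factor = threshold_factor,
                 diameter_gate_um = diameter_gate_um,
                 min_circularity = min_circularity,
                 z_step_um = z_step_um,
                 max_iterations = as.integer(max_iterations)),
            class = "soma_config")
}

#' Detect a circular soma-like feature in one fluorescence frame
#'
#' The frame is binarized at `threshold_factor` times its mean intensity
#' (the threshold is therefore invariant to global gain). Among the
#' 8-connected components, those whose equivalent diameter falls inside the
#' configured gate and whose circularity reaches `min_circularity` qualify;
#' the brightest qualifier (highest mean intensity, i.e. nearest focus under
#' the blur model) is returned. `NULL` means no feature -- a normal outcome,
#' not an error.
#'
#' @param frame a fluorescence [camera_frame()] (or matrix plus `pixel_size`).
#' @param config a [soma_config()].
#' @param pixel_size um/pixel, taken from the frame when available.
#' @return A `soma_detection` or `NULL`. Fields: `center_px` (row, col),
#'   `equivalent_diameter` (um), `circularity`, `mean_intensity`,
#'   `z_found`, `iterations_used` (the last two filled by the scan).
#' @export
detect_circular_feature <- function(frame, config = soma_config(),
                                    pixel_size = NULL) {
  r <- frame_raster(frame)
  if (is.null(pixel_size))
    pixel_size <- if (inherits(frame, "camera_frame")) frame$pixel_size else
      stop("pixel_size required for bare matrices")
  thr <- config$threshold_factor * mean(r)
  m <- r > thr
  if (!any(m)) return(NULL)
  lab <- label_components(m, 8)
  st <- component_stats(lab, intensity = r)
  st$diameter_um <- st$equiv_diameter_px * pixel_size
  ok <- st$diameter_um >= config$diameter_gate_um[1] &
    st$diameter_um <= config$diameter_gate_um[2] &
    st$circularity >= config$min_circularity
  if (!any(ok)) return(NULL)
  best <- st[ok, ][which.max(st$mean_intensity[ok]), ]
  structure(list(center_px = c(row = best$centroid_row, col = best$centroid_col),
                 equivalent_diameter = best$diameter_um,
                 circularity = best$circularity,
                 mean_intensity = best$mean_intensity,
                 z_found = if (inherits(frame, "camera_frame")) frame$z_position else NA_real_,
                 iterations_used = NA_integer_),
            class = "soma_detection")
}

#' @export
print.soma_detection <- function(x, ...) {
  cat(sprintf("<soma_detection> centre px (%.1f, %.1f), diameter %.2f um, circ %.2f, z %.2f um (iter %s)\n",
              x$center_px[1], x$center_px[2], x$equivalent_diameter,
              x$circularity, x$z_found, x$iterations_used))
  invisible(x)
}

#' Step 2: coarse focal scan for a soma
#'
#' Starting at the cover-glass interface, the coarse stage advances the
#' focal plane in 2.5 um steps into the worm body, acquiring a fluorescence
#' frame at each step and running [detect_circular_feature()]. The scan stops
#' at the first detection; if no circular feature is found within
#' `max_iterations` frames (iteration 1 is the starting plane) the worm is
#' flushed. Pre-recorded stacks may be substituted for the closed-loop
#' render.
#'
#' @param rig a [rig_state()] at the 63x objective, focus at the glass.
#' @param phantom_or_stack a [make_phantom()] result (closed-loop rendering)
#'   or a [zstack()] of pre-acquired frames.
#' @param config a [soma_config()].
#' @param render a [render_params()].
#' @param noise logical, add sensor noise to rendered frames.
#' @return A list with `detection` (a `soma_detection` or `NULL` on
#'   rejection), `rig` (focus left at the detection plane), and
#'   `iterations`.
#' @export
coarse_focus_scan <- function(rig, phantom_or_stack, config = soma_config(),
                              render = render_params(), noise = TRUE) {
  from_stack <- inherits(phantom_or_stack, "zstack")
  n_avail <- if (from_stack) length(phantom_or_stack$frames) else Inf
  iter <- 0L
  while (iter < config$max_iterations && iter < n_avail) {
    iter <- iter + 1L
    if (from_stack) {
      frame <- phantom_or_stack$frames[[iter]]
    } else {
      frame <- render_frame(phantom_or_stack, rig, "fluorescence", render, noise)
    }
    det <- detect_circular_feature(frame, config)
    if (!is.null(det)) {
      det$iterations_used <- iter
      return(list(detection = det, rig = rig, iterations = iter))
    }
    if (!from_stack && iter < config$max_iterations)
      rig <- move_stage(rig, c(0, 0, config$z_step_um))
  }
  list(detection = NULL, rig = rig, iterations = iter)
}

#' Step 2 follow-up: translate the detected soma onto the laser spot
#'
#' Commands the coarse stage so that the soma centre maps onto the
#' calibrated laser-spot pixel (close to the centre of the field of view),
#' within stage quantization. A required translation beyond the trap extent
#' raises a rejection condition.
#'
#' @param rig a [rig_state()].
#' @param det a `soma_detection`.
#' @param laser_spot_px `(row, col)` of the ablation spot in the frame.
#' @param max_translation_um rejection bound on the commanded move, um.
#' @return Updated rig state.
#' @export
center_on_laser_spot <- function(rig, det, laser_spot_px,
                                 max_translation_um = 150) {
  px <- pixel_size_um(rig$optics, rig$objective)
  dx <- (laser_spot_px[2] - det$center_px[["col"]]) * px
  dy <- (laser_spot_px[1] - det$center_px[["row"]]) * px
  if (max(abs(c(dx, dy))) > max_translation_um)
    stop(errorCondition(
      sprintf("soma recentering move (%.1f, %.1f) um exceeds trap extent", dx, dy),
      class = c("axobot_reject", "error", "condition")))
  move_stage(rig, c(dx, dy, 0))
}
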