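#' Step 4 configuration: proportional alignment of the axon onto the spot
#'
#' @param gain_kp proportional gain of the alignment loop. The paper's gain
#'   is not stated; 0.9 sits inside the deadbeat-stable region `0 < Kp < 2`
#'   (error contracts by `|1 - Kp|` per iteration, up to backlash).
#' @param tolerance_px convergence tolerance: the axon centre must come
#'   within ~1 pixel of the ablation target.
#' @param max_iterations alignment iterations before the worm is flushed.
#' @param anterior_offset_um translation from the soma towards the head
#'   before targeting, um.
#' @param profile_window_px rows examined around the spot row when locating
#'   the axon profile.
#' @param profile_halfcols columns averaged on each side of the spot column.
#' @param refocus_retries re-focus attempts when the profile shows no axon.
#' @return A `control_config` list.
#' @export
control_config <- function(gain_kp = 0.9, tolerance_px = 1, max_iterations = 10L,
                           anterior_offset_um = 50, profile_window_px = 120L,
                           profile_halfcols = 5L, refocus_retries = 2L) {
  if (!(gain_kp > 0 && gain_kp <= 1.5)) stop("gain_kp must be in (0, 1.5]")
  stopifnot(tolerance_px > 0, max_iterations >= 1, anterior_offset_um >= 0)
  structure(list(gain_kp = gain_kp, tolerance_px = tolerance_px,
                 max_iterations = as.integer(max_iterations),
                 anterior_offset_um = anterior_offset_um,
                 profile_window_px = as.integer(profile_window_px),
                 profile_halfcols = as.integer(profile_halfcols),
                 refocus_retries = as.integer(refocus_retries)),
            class = "control_config")
}

#' Step 4: move the field of view 50 um anterior along the axon
#'
#' Translates the coarse stage so the field of view shifts by
#' `offset` um from the soma towards the worm's head. The stage carries the
#' sample, so viewing a region at image-left (`head_direction = "left"`)
#' means translating the sample towards +x.
#'
#' @param rig a [rig_state()].
#' @param neuron a `neuron_id`; must be classified ALM with a known head
#'   direction (callers guarantee this).
#' @param offset anterior offset, um.
#' @return Updated rig state.
#' @export
anterior_offset_move <- function(rig, neuron, offset = 50) {
  if (!identical(neuron$classification, "ALM") ||
      neuron$head_direction == "unknown")
    stop("anterior_offset_move requires an ALM with known head direction")
  h <- if (neuron$head_direction == "left") -1 else 1
  # view world point (w + h*offset): sample must shift by -h*offset in view
  # coordinates, i.e. stage x moves by -h*offset under the p = c + (w+s)/px map
  move_stage(rig, c(-h * offset, 0, 0))
}

#' Sub-pixel axon centre from the column intensity profile
#'
#' Averages the image over `spot_col +/- profile_halfcols` columns, subtracts
#' the background (median of the windowed profile), and returns the
#' intensity-weighted centroid row within a window centred on `spot_row`.
#' A profile indistinguishable from background raises a `no_axon` condition
#' (the controller re-focuses, then flushes).
#'
#' @param image numeric matrix or [camera_frame()].
#' @param spot_col ablation-spot column (pixels).
#' @param spot_row centre of the search window (defaults to frame centre row).
#' @param window window height, pixels.
#' @param halfcols columns averaged each side of `spot_col`.
#' @return Sub-pixel row of the axon centre.
#' @export
axon_profile_center <- function(image, spot_col, spot_row = NULL, window = 120,
                                halfcols = 5) {
  r <- frame_raster(image)
  if (is.null(spot_row)) spot_row <- (nrow(r) + 1) / 2
  cols <- max(1, round(spot_col - halfcols)):min(ncol(r), round(spot_col + halfcols))
  rows <- max(1, round(spot_row - window / 2)):min(nrow(r), round(spot_row + window / 2))
  prof <- rowMeans(r[rows, cols, drop = FALSE])
  bg <- median(prof)
  noise <- max(mad(prof), 1e-9)
  w <- pmax(prof - bg, 0)
  if (max(prof) < bg + 5 * noise || sum(w) <= 0)
    stop(errorCondition("no axon signal in column profile",
                        class = c("axobot_no_axon", "error", "condition")))
  # suppress noise wings: keep weight only near the peak lobe
  peak <- which.max(w)
  keep <- w >= 0.2 * w[peak]
  # restrict to the contiguous run containing the peak
  runs <- rle(keep)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  seg <- which(starts <= peak & ends >= peak)
  sel <- starts[seg]:ends[seg]
  sum(rows[sel] * w[sel]) / sum(w[sel])
}

#' Step 4: close the proportional control loop on the piezo y-axis
#'
#' Repeatedly renders a frame, measures the pixel error between the axon
#' centre and the ablation spot row, and commands a relative piezo move of
#' `-Kp * error * pixel_size` until the error is within `tolerance_px`
#' (converged) or `max_iterations` is exhausted (failed; the worm is
#' flushed). A commanded move beyond the piezo's +/-10 um travel also fails
#' the lock.
#'
#' @param rig a [rig_state()] with the axon in focus near the spot column.
#' @param phantom a [make_phantom()] result.
#' @param config a [control_config()].
#' @param laser_spot_px `(row, col)` of the ablation spot.
#' @param render a [render_params()].
#' @param noise logical, sensor noise in rendered frames.
#' @return A `target_lock`: `converged`, `iterations`, `final_error_px`,
#'   `y_trajectory` (piezo y after each commanded move, um), `z_best` (um),
#'   and the final `rig`.
#' @export
align_axon <- function(rig, phantom, config = control_config(),
                       laser_spot_px = NULL, render = render_params(),
                       noise = TRUE) {
  opt <- rig$optics
  px <- pixel_size_um(opt, rig$objective)
  if (is.null(laser_spot_px))
    laser_spot_px <- c((opt$sensor_height_px + 1) / 2, (opt$sensor_width_px + 1) / 2)
  traj <- numeric(0)
  iters <- 0L
  err <- NA_real_
  converged <- FALSE
  measure <- function() {
    frame <- render_frame(phantom, rig, "fluorescence", render, noise)
    axon_profile_center(frame, spot_col = laser_spot_px[2],
                        spot_row = laser_spot_px[1],
                        window = config$profile_window_px,
                        halfcols = config$profile_halfcols) - laser_spot_px[1]
  }
  res <- tryCatch({
    err <- measure()
    while (abs(err) > config$tolerance_px && iters < config$max_iterations) {
      iters <- iters + 1L
      rig <- move_piezo(rig, c(0, -config$gain_kp * err * px, 0))
      traj <- c(traj, unname(rig$piezo$position["y"]))
      err <- measure()
    }
    converged <- abs(err) <= config$tolerance_px
    NULL
  }, axobot_no_axon = function(e) e,
     error = function(e) {
       if (grepl("piezo_range_error", conditionMessage(e))) e else stop(e)
     })
  structure(list(converged = converged && is.null(res),
                 iterations = iters,
                 final_error_px = err,
                 y_trajectory = traj,
                 z_best = unname(rig$stage$position["z"] + rig$piezo$position["z"]),
                 failure = if (is.null(res)) NA_character_ else conditionMessage(res),
                 rig = rig),
            class = "target_lock")
}

#' @export
print.target_lock <- function(x, ...) {
  cat(sprintf("<target_lock> %s after %d iterations, final error %.2f px\n",
              if (x$converged) "converged" else "FAILED", x$iterations,
              x$final_error_px))
  invisible(x)
}

#' Step 4 finale: fire the pulse train at the locked target
#'
#' Computes the world position imaged at the ablation-spot pixel and
#' delegates to [fire_ablation()]. Firing with a non-converged lock is a
#' contract violation.
#'
#' @param rig a [rig_state()] (typically `lock$rig`).
#' @param phantom a [make_phantom()] result.
#' @param lock a converged `target_lock`.
#' @param laser_spot_px `(row, col)` spot pixel; default frame centre.
#' @param pulses,energy_nJ pulse train (300 pulses of 4 nJ by default).
#' @param hit_tolerance lateral hit radius, um.
#' @return As [fire_ablation()]: list of `outcome` and updated `phantom`.
#' @export
execute_axotomy <- function(rig, phantom, lock, laser_spot_px = NULL,
                            pulses = 300, energy_nJ = 4, hit_tolerance = 0.31) {
  if (!isTRUE(lock$converged))
    stop("execute_axotomy called with a non-converged target lock")
  opt <- rig$optics
  px <- pixel_size_um(opt, rig$objective)
  if (is.null(laser_spot_px))
    laser_spot_px <- c((opt$sensor_height_px + 1) / 2, (opt$sensor_width_px + 1) / 2)
  sx <- rig$stage$position["x"] + rig$piezo$position["x"]
  sy <- rig$stage$position["y"] + rig$piezo$position["y"]
  target <- c((laser_spot_px[2] - (opt$sensor_width_px + 1) / 2) * px - sx,
              (laser_spot_px[1] - (opt$sensor_height_px + 1) / 2) * px - sy)
  fire_ablation(phantom, rig, unname(target), pulses = pulses,
                energy_nJ = energy_nJ, hit_tolerance = hit_tolerance)
}
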