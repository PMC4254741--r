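#' Coarse translation stage model
#'
#' Open-loop three-axis stage with 0.1 um minimal incremental motion and
#' 5 mm/s maximum speed. Commanded moves are quantized to `min_step`.
#'
#' @param min_step minimal incremental motion, um.
#' @param max_speed maximum translation speed, mm/s (annotation only).
#' @param position starting `(x, y, z)` position, um.
#' @return A `stage_model` object.
#' @export
stage_model <- function(min_step = 0.1, max_speed = 5,
                        position = c(x = 0, y = 0, z = 0)) {
  stopifnot(min_step > 0, length(position) == 3)
  structure(list(min_step = min_step, max_speed = max_speed,
                 position = setNames(as.numeric(position), c("x", "y", "z"))),
            class = "stage_model")
}

#' Piezoelectric fine actuator with backlash hysteresis
#'
#' Three-axis open-loop piezo with 25 nm minimal step and +/-10 um travel per
#' axis. Direction reversals (including the first move from rest) consume a
#' `backlash_deadband` of commanded motion before any net displacement occurs,
#' emulating the positioning hysteresis of an open-loop actuator.
#'
#' @param min_step minimal step, um.
#' @param range travel limit per axis, um (position must stay in `[-range, range]`).
#' @param backlash_deadband lost motion on direction reversal, um.
#' @param position starting `(x, y, z)` position, um.
#' @return A `piezo_model` object; `last_direction` holds the sign (-1, 0, +1)
#'   of the last commanded move on each axis.
#' @export
piezo_model <- function(min_step = 0.025, range = 10, backlash_deadband = 0.1,
                        position = c(x = 0, y = 0, z = 0)) {
  stopifnot(min_step > 0, range > 0, backlash_deadband >= 0)
  structure(list(min_step = min_step, range = range,
                 backlash_deadband = backlash_deadband,
                 last_direction = c(x = 0, y = 0, z = 0),
                 position = setNames(as.numeric(position), c("x", "y", "z"))),
            class = "piezo_model")
}

#' Full rig state
#'
#' Aggregates the coarse stage, the piezo, the active objective, the on-chip
#' valve states and the calibrated laser z-offset (beam waist below the camera
#' focal plane, um; ablations are fired 0.5-0.9 um below visible focus).
#'
#' @param optics an [optics_config()].
#' @param objective name of the active objective.
#' @param stage,piezo actuator models.
#' @param laser_focus_offset_z beam-waist offset below camera focus, um.
#' @return A `rig_state` object.
#' @export
rig_state <- function(optics = optics_config(), objective = "5x",
                      stage = stage_model(), piezo = piezo_model(),
                      laser_focus_offset_z = 0.7) {
  if (is.null(optics$magnifications[[objective]]))
    stop("objective not in optics config: ", objective)
  structure(list(optics = optics, objective = objective,
                 stage = stage, piezo = piezo,
                 valve_states = c(V1 = "closed", V2 = "closed", V3 = "closed",
                                  V4 = "closed", V5 = "closed"),
                 laser_focus_offset_z = laser_focus_offset_z),
            class = "rig_state")
}

#' Switch the active objective
#' @param rig a [rig_state()].
#' @param objective objective name.
#' @return Updated rig state.
#' @export
set_objective <- function(rig, objective) {
  if (is.null(rig$optics$magnifications[[objective]]))
    stop("objective not in optics config: ", objective)
  rig$objective <- objective
  rig
}

quantize <- function(x, step) round(x / step) * step

#' Move the coarse stage by a relative displacement
#'
#' The commanded displacement is quantized to the stage's minimal incremental
#' motion (0.1 um by default). The stage has no backlash model (hardware
#' compensation is assumed).
#'
#' @param rig a [rig_state()].
#' @param delta `(dx, dy, dz)` displacement, um.
#' @return Updated rig state.
#' @export
move_stage <- function(rig, delta) {
  stopifnot(length(delta) == 3)
  d <- quantize(as.numeric(delta), rig$stage$min_step)
  rig$stage$position <- rig$stage$position + d
  rig
}

#' Move the piezo actuator by a relative displacement
#'
#' Achieved displacement equals the commanded displacement minus the backlash
#' deadband consumed whenever the commanded direction differs from the last
#' commanded direction on that axis (the first move from rest also pays the
#' deadband), then quantized to the 25 nm minimal step. A commanded target
#' outside the +/-10 um range raises an error, which callers treat as a
#' targeting failure.
#'
#' @param rig a [rig_state()].
#' @param delta `(dx, dy, dz)` displacement, um.
#' @return Updated rig state.
#' @export
move_piezo <- function(rig, delta) {
  stopifnot(length(delta) == 3)
  p <- rig$piezo
  delta <- as.numeric(delta)
  target <- p$position + delta
  if (any(abs(target) > p$range + 1e-9))
    stop("piezo_range_error: commanded position ",
         paste(sprintf("%.3f", target), collapse = ", "),
         " um exceeds +/-", p$range, " um")
  for (ax in 1:3) {
    d <- delta[ax]
    if (d == 0) next
    s <- sign(d)
    eff <- d
    if (s != p$last_direction[ax]) {
      eff <- s * max(0, abs(d) - p$backlash_deadband)
    }
    eff <- quantize(eff, p$min_step)
    p$position[ax] <- p$position[ax] + eff
    p$last_direction[ax] <- s
  }
  rig$piezo <- p
  rig
}

#' Set one or more valve states
#' @param rig a [rig_state()].
#' @param ... named valve states, e.g. `V3 = "open"`.
#' @return Updated rig state.
#' @export
set_valves <- function(rig, ...) {
  v <- c(...)
  bad <- setdiff(names(v), names(rig$valve_states))
  if (length(bad)) stop("unknown valves: ", paste(bad, collapse = ", "))
  if (!all(v %in% c("open", "closed"))) stop("valve state must be open/closed")
  rig$valve_states[names(v)] <- v
  rig
}

#' Calibrate the laser-focus z-offset against a simulated glass ablation mark
#'
#' Emulates the pre-run calibration: a test ablation mark is burned on the
#' cover-glass surface at camera focus, then the objective is stepped in
#' 0.25 um increments towards the mark and the apparent 2-D profile diameter
#' is measured at each step. The offset at which the profile is smallest is
#' the beam-waist location; typically ~0.5 um below camera focus.
#'
#' The apparent mark diameter follows a Gaussian-beam-like hyperbola
#' `d(z) = d0 * sqrt(1 + ((z - z_waist)/z_r)^2)`.
#'
#' @param rig a [rig_state()] (used for bookkeeping only).
#' @param glass_surface_z z of the glass surface at camera focus, um.
#' @param waist_offset true beam-waist offset below camera focus, um
#'   (simulator ground truth; default 0.5).
#' @param scan_range scan extent below focus, um, scanned in 0.25 um steps.
#' @param waist_diameter_um,rayleigh_um mark model parameters.
#' @return The calibrated offset in um below camera focus.
#' @export
calibrate_z_offset <- function(rig, glass_surface_z = 0, waist_offset = 0.5,
                               scan_range = c(0, 2), waist_diameter_um = 0.62,
                               rayleigh_um = 0.8) {
  stopifnot(length(scan_range) == 2, scan_range[2] > scan_range[1])
  z <- seq(scan_range[1], scan_range[2], by = 0.25)
  d <- waist_diameter_um * sqrt(1 + ((z - waist_offset) / rayleigh_um)^2)
  k <- which.min(d)
  # a minimum on the scan boundary with a strictly monotone profile means the
  # waist lies outside the scanned interval: no usable minimum
  mono <- all(diff(d) > 0) || all(diff(d) < 0)
  if ((k == 1L || k == length(d)) && mono &&
      (waist_offset < scan_range[1] - 1e-9 || waist_offset > scan_range[2] + 1e-9))
    stop("calibration_error: no minimum of the ablation profile within scan range")
  z[k]
}

#' @export
print.rig_state <- function(x, ...) {
  cat(sprintf("<rig_state> objective %s; stage (%.2f, %.2f, %.2f) um; piezo (%.3f, %.3f, %.3f) um\n",
              x$objective, x$stage$position[1], x$stage$position[2], x$stage$position[3],
              x$piezo$position[1], x$piezo$position[2], x$piezo$position[3]))
  cat("  valves:", paste(names(x$valve_states), x$valve_states, sep = "=", collapse = " "),
      sprintf("; laser dz %.2f um\n", x$laser_focus_offset_z))
  invisible(x)
}
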