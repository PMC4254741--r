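#' The seven-phase valve program of one automation cycle
#'
#' A symbolic trace of the valve actuation and flow progression that stages,
#' injects, traps, operates on and finally ejects or flushes one worm. No
#' fluid dynamics is simulated; pressures and durations are carried as
#' annotations for logging fidelity. A constant ~15 kPa head pressure drives
#' worms from the loading chamber towards the staging area throughout.
#'
#' @param inject_ms injection duration, ms (1000-1200).
#' @param inject_kPa injection head pressure, kPa.
#' @param eject_kPa ejection/flush head pressure, kPa.
#' @param head_kPa constant loading head pressure, kPa.
#' @return A `valve_program`: list of steps, each with `name`, `open`,
#'   `close`, `head_pressure_kPa`, `duration_ms`, `flow_direction`.
#' @export
default_valve_program <- function(inject_ms = 1100, inject_kPa = 65,
                                  eject_kPa = 135, head_kPa = 15) {
  stopifnot(inject_ms >= 1000, inject_ms <= 1200)
  steps <- list(
    list(name = "fill", open = character(0), close = c("V1", "V2", "V3", "V4", "V5"),
         head_pressure_kPa = head_kPa, duration_ms = 2000, flow_direction = "forward"),
    list(name = "stage", open = "V1", close = "V2",
         head_pressure_kPa = head_kPa, duration_ms = 500, flow_direction = "forward"),
    list(name = "gate_close", open = character(0), close = "V1",
         head_pressure_kPa = head_kPa, duration_ms = 100, flow_direction = "forward"),
    list(name = "inject", open = c("V1", "V2", "V3"), close = character(0),
         head_pressure_kPa = inject_kPa, duration_ms = inject_ms,
         flow_direction = "reversed"),
    list(name = "trap", open = character(0), close = "V3",
         head_pressure_kPa = head_kPa, duration_ms = 600,
         flow_direction = "forward", cycle = c("close", "open", "close")),
    list(name = "axotomize", open = character(0), close = character(0),
         head_pressure_kPa = head_kPa, duration_ms = NA_real_,
         flow_direction = "none"),
    list(name = "terminal", open = c("V3", "V4_or_V5"), close = character(0),
         head_pressure_kPa = eject_kPa, duration_ms = 800,
         flow_direction = "reversed",
         routes = c(success = "eject(V5)", failure = "flush(V4)"))
  )
  structure(list(steps = steps, head_pressure_kPa = head_kPa),
            class = "valve_program")
}

#' @export
print.valve_program <- function(x, ...) {
  cat("<valve_program>", length(x$steps), "phases, head pressure",
      x$head_pressure_kPa, "kPa\n")
  for (s in x$steps)
    cat(sprintf("  %-10s open[%s] close[%s] %s kPa %s ms %s\n", s$name,
                paste(s$open, collapse = ","), paste(s$close, collapse = ","),
                s$head_pressure_kPa, s$duration_ms, s$flow_direction))
  invisible(x)
}

step_names <- c("trap", "coarse_focus", "verify", "axotomy")

draw_duration <- function(spec) {
  m <- spec[["mean"]]; s <- spec[["sd"]]
  shape <- (m / s)^2
  rgamma(1, shape = shape, rate = shape / m)
}

new_record <- function(worm_id) {
  list(worm_id = worm_id, step_reached = "trap", outcome = "flushed",
       flush_reason = NA_character_,
       durations = c(step1 = NA_real_, step2 = NA_real_,
                     step3 = NA_real_, step4 = NA_real_),
       target_lock = NULL, ablation = NULL, degenerate = NA_character_)
}

# closed-loop imaging cycle; phantom assumed staged, rig at 5x over the trap
run_cycle_imaging <- function(phantom, cfg, worm_id) {
  rec <- new_record(worm_id)
  rec$degenerate <- phantom$degenerate
  optics <- cfg_optics(cfg)
  rp <- cfg_render(cfg)
  rig <- rig_state(optics, objective = "5x",
                   laser_focus_offset_z = cfg$laser$focus_offset_z)

  flush <- function(rec, step, reason) {
    rec$step_reached <- step
    rec$outcome <- "flushed"
    rec$flush_reason <- reason
    rec
  }

  # ---- Step 1: worm localization in bright field ----
  rec$durations["step1"] <- draw_duration(cfg$durations$step1)
  px5 <- pixel_size_um(optics, "5x")
  ext <- cfg$locator$trap_extent_um
  roi_rows <- min(round(ext[2] / px5), optics$sensor_height_px)
  roi_cols <- min(round(ext[1] / px5), optics$sensor_width_px)
  roi <- c(floor((optics$sensor_height_px - roi_rows) / 2),
           floor((optics$sensor_width_px - roi_cols) / 2), roi_rows, roi_cols)
  baseline <- render_frame(NULL, rig, "brightfield", rp)
  snapshot <- render_frame(phantom, rig, "brightfield", rp)
  loc <- locate_worm(snapshot, baseline, roi, cfg_locator(cfg))
  if (loc$status != "accepted") return(flush(rec, "trap", loc$status))
  rig <- move_stage(rig, c(loc$stage_move_um[["x"]], loc$stage_move_um[["y"]], 0))

  # ---- Step 2: coarse soma search at 63x ----
  rec$step_reached <- "coarse_focus"
  rec$durations["step2"] <- draw_duration(cfg$durations$step2)
  rig <- set_objective(rig, "63x")
  scan <- coarse_focus_scan(rig, phantom, cfg_soma(cfg), rp)
  rig <- scan$rig
  if (is.null(scan$detection))
    return(flush(rec, "coarse_focus", "no_circular_feature"))
  det <- scan$detection
  rig <- tryCatch(center_on_laser_spot(rig, det, laser_spot_px(optics)),
                  axobot_reject = function(e) e)
  if (inherits(rig, "condition"))
    return(flush(rec, "coarse_focus", "recenter_beyond_trap"))

  # ---- Step 3: fine focus + neuron verification ----
  rec$step_reached <- "verify"
  rec$durations["step3"] <- draw_duration(cfg$durations$step3)
  zs <- seq(-cfg$fine_focus$halfspan_um, cfg$fine_focus$halfspan_um,
            by = cfg$fine_focus$step_um)
  frames <- vector("list", length(zs))
  for (i in seq_along(zs)) {
    r2 <- move_piezo(rig, c(0, 0, zs[i] - rig$piezo$position[["z"]]))
    frames[[i]] <- render_frame(phantom, r2, "fluorescence", rp)
    rig <- r2
  }
  best <- fine_focus(zstack(frames, zs), sigma = cfg$fine_focus$log_sigma)
  rig <- move_piezo(rig, c(0, 0, zs[best] - rig$piezo$position[["z"]]))
  focus_frame <- frames[[best]]
  # re-detect at best focus for an accurate centre
  det2 <- detect_circular_feature(focus_frame, cfg_soma(cfg))
  if (!is.null(det2)) det <- det2
  nid <- tryCatch(verify_neuron(focus_frame, det, cfg_verifier(cfg)),
                  axobot_reject = function(e) e)
  if (inherits(nid, "condition")) return(flush(rec, "verify", "roi_clipped"))
  if (nid$classification != "ALM")
    return(flush(rec, "verify", "no_straight_edge"))

  # ---- Step 4: anterior move, axon focus, alignment, ablation ----
  rec$step_reached <- "axotomy"
  rec$durations["step4"] <- draw_duration(cfg$durations$step4)
  rig <- anterior_offset_move(rig, nid, cfg$control$anterior_offset_um)
  spot <- laser_spot_px(optics)
  zax <- seq(-cfg$axon_focus$halfspan_um, cfg$axon_focus$halfspan_um,
             by = cfg$axon_focus$step_um)
  aframes <- vector("list", length(zax))
  z0 <- rig$piezo$position[["z"]]
  zabs <- z0 + zax
  ok_z <- abs(zabs) <= rig$piezo$range
  zabs <- zabs[ok_z]; aframes <- aframes[ok_z]
  aroi <- clip_roi(c(round(spot[1] - cfg$axon_focus$roi_rows / 2),
                     round(spot[2] - cfg$axon_focus$roi_cols / 2),
                     cfg$axon_focus$roi_rows, cfg$axon_focus$roi_cols),
                   c(optics$sensor_height_px, optics$sensor_width_px))
  for (i in seq_along(zabs)) {
    r2 <- move_piezo(rig, c(0, 0, zabs[i] - rig$piezo$position[["z"]]))
    aframes[[i]] <- render_frame(phantom, r2, "fluorescence", rp)
    rig <- r2
  }
  bestz <- axon_focus(zstack(aframes, zabs), aroi)
  rig <- move_piezo(rig, c(0, 0, zabs[bestz] - rig$piezo$position[["z"]]))
  lock <- align_axon(rig, phantom, cfg_control(cfg), laser_spot_px = spot,
                     render = rp)
  rec$target_lock <- lock[c("converged", "iterations", "final_error_px",
                            "y_trajectory", "z_best")]
  if (!lock$converged) return(flush(rec, "axotomy", "no_target_lock"))
  fired <- execute_axotomy(lock$rig, phantom, lock, laser_spot_px = spot,
                           pulses = cfg$laser$pulses,
                           energy_nJ = cfg$laser$energy_nJ,
                           hit_tolerance = cfg$laser$hit_tolerance)
  rec$ablation <- unclass(fired$outcome)
  rec$phantom_after <- fired$phantom
  if (!fired$outcome$hit) return(flush(rec, "axotomy", "ablation_miss"))
  rec$step_reached <- "done"
  rec$outcome <- "success"
  rec
}

laser_spot_px <- function(optics) {
  c((optics$sensor_height_px + 1) / 2, (optics$sensor_width_px + 1) / 2)
}

# event-level cycle: the degenerate flag decides the failing step directly;
# equivalent in distribution to the imaging pipeline (verified by test)
run_cycle_event <- function(phantom, cfg, worm_id) {
  rec <- new_record(worm_id)
  rec$degenerate <- phantom$degenerate
  fail_step <- switch(phantom$degenerate,
                      trap = "trap", soma = "coarse_focus",
                      axon = "verify", ablation = "axotomy", none = NA)
  reasons <- c(trap = "reject_near_edge", coarse_focus = "no_circular_feature",
               verify = "no_straight_edge", axotomy = "no_target_lock")
  for (i in seq_along(step_names)) {
    s <- step_names[i]
    rec$step_reached <- s
    rec$durations[paste0("step", i)] <- draw_duration(cfg$durations[[paste0("step", i)]])
    if (!is.na(fail_step) && identical(s, fail_step)) {
      rec$outcome <- "flushed"
      rec$flush_reason <- reasons[[s]]
      return(rec)
    }
  }
  rec$step_reached <- "done"
  rec$outcome <- "success"
  rec$ablation <- unclass(ablation_outcome(TRUE, TRUE,
                                           lateral_error = abs(rnorm(1, 0, 0.05)),
                                           axial_offset = cfg$laser$focus_offset_z,
                                           pulses = cfg$laser$pulses,
                                           pulse_energy = cfg$laser$energy_nJ))
  rec
}

#' Run the full automation cycle on one staged worm
#'
#' Executes the valve program and Steps 1-4 in order, flushing the worm at
#' the first failing step (monotone step ordering: no later step runs after
#' a failure). In `"imaging"` mode every decision is made by the image
#' pipeline on rendered frames; in `"event"` mode the phantom's ground-truth
#' degenerate flag decides the outcome directly. Per-step durations are
#' drawn from the configured gamma distributions and labelled simulated.
#'
#' @param phantom a [make_phantom()] result.
#' @param cfg a [run_config()].
#' @param worm_id identifier for the record.
#' @return An `automation_record`: `worm_id`, `step_reached`
#'   (`trap`/`coarse_focus`/`verify`/`axotomy`/`done`), `outcome`
#'   (`success`/`flushed`), `flush_reason`, simulated `durations`,
#'   `target_lock` and `ablation` where applicable.
#' @export
run_worm_cycle <- function(phantom, cfg = run_config(), worm_id = 1L) {
  rec <- if (identical(cfg$pipeline, "imaging"))
    tryCatch(run_cycle_imaging(phantom, cfg, worm_id),
             error = function(e) {
               r <- new_record(worm_id)
               r$degenerate <- phantom$degenerate
               r$outcome <- "flushed"
               r$flush_reason <- paste0("rig_error: ", conditionMessage(e))
               r
             })
  else run_cycle_event(phantom, cfg, worm_id)
  rec$valve_program <- "7-phase default"
  class(rec) <- "automation_record"
  rec
}

#' @export
print.automation_record <- function(x, ...) {
  cat(sprintf("<automation_record> worm %s: %s at %s%s\n", x$worm_id, x$outcome,
              x$step_reached,
              if (!is.na(x$flush_reason)) paste0(" (", x$flush_reason, ")") else ""))
  invisible(x)
}

#' Run a population of worms through the automation
#'
#' Stages, processes and routes `n` independent phantoms, collecting the
#' per-worm records and an attrition summary. Deterministic for a fixed
#' seed.
#'
#' @param n number of worms.
#' @param cfg a [run_config()].
#' @param seed integer seed.
#' @return A list with `records` (list of `automation_record`) and
#'   `summary` (see [attrition_summary()]).
#' @export
run_population <- function(n, cfg = run_config(), seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  pp <- cfg_phantom_params(cfg)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- make_phantom(pp, seed = NULL)
    records[[i]] <- run_worm_cycle(ph, cfg, worm_id = i)
  }
  list(records = records, summary = attrition_summary(records), seed = seed)
}
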