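default_config_tree <- function() {
  list(
    optics = list(sensor_width_px = 1392L, sensor_height_px = 1040L,
                  camera_pixel_pitch = 6.45,
                  magnifications = list(
                    list(name = "5x", magnification = 5, numerical_aperture = 0.16),
                    list(name = "63x", magnification = 63, numerical_aperture = 1.4)),
                  emission_wavelength = 500, defocus_blur_scale = 1.5,
                  base_blur_sigma = 0.15),
    render = unclass(render_params()),
    phantom = lapply(unclass(phantom_params()), identity),
    locator = c(unclass(locator_config()), list(trap_extent_um = c(600, 400))),
    soma = unclass(soma_config()),
    verifier = unclass(verifier_config()),
    control = unclass(control_config()),
    laser = list(pulses = 300L, energy_nJ = 4, focus_offset_z = 0.7,
                 hit_tolerance = 0.31),
    fine_focus = list(step_um = 0.7, halfspan_um = 2.1, log_sigma = 2),
    axon_focus = list(step_um = 0.35, halfspan_um = 1.05,
                      roi_rows = 150L, roi_cols = 200L),
    durations = list(step1 = c(mean = 4.8, sd = 1.5),
                     step2 = c(mean = 3.5, sd = 1.2),
                     step3 = c(mean = 3.0, sd = 1.0),
                     step4 = c(mean = 5.7, sd = 2.1)),
    pipeline = "event"
  )
}

merge_checked <- function(base, upd, path = "") {
  bad <- setdiff(names(upd), names(base))
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  for (nm in names(upd)) {
    if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
        !is.null(names(base[[nm]])) && nm != "magnifications") {
      base[[nm]] <- merge_checked(base[[nm]], upd[[nm]], paste0(path, ".", nm))
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

#' Aggregate run configuration
#'
#' Builds the full configuration tree for simulation and pipeline runs, with
#' every hardware- and algorithm-anchored default present and overridable.
#' Unknown keys are rejected. `pipeline` selects how [run_worm_cycle()]
#' decides step outcomes: `"imaging"` runs the four image-processing steps
#' closed-loop against rendered frames; `"event"` short-cuts to the phantom's
#' ground-truth degenerate flags (the two agree by construction and by test,
#' and event mode makes population-scale runs cheap).
#'
#' @param ... named overrides of the defaults, nested lists merged per key
#'   (e.g. `control = list(gain_kp = 0.8)`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- merge_checked(default_config_tree(), list(...))
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Checks the structural invariants (positive dimensions and durations, the
#' proportional gain inside its stable region, rejection probabilities
#' summing to at most 1, a valid pipeline mode) and returns the config with
#' class `run_config`.
#'
#' @param cfg a configuration list.
#' @return The validated config.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(cfg$optics$sensor_width_px > 0 && cfg$optics$sensor_height_px > 0,
      "optics: sensor dimensions must be positive")
  chk(cfg$optics$camera_pixel_pitch > 0, "optics: camera_pixel_pitch must be > 0")
  chk(cfg$control$gain_kp > 0 && cfg$control$gain_kp <= 1.5,
      "control: gain_kp must be in (0, 1.5]")
  chk(cfg$control$tolerance_px > 0, "control: tolerance_px must be > 0")
  pr <- unlist(cfg$phantom$p_reject)
  chk(all(pr >= 0) && sum(pr) <= 1,
      "phantom: p_reject must be nonnegative and sum to <= 1")
  chk(cfg$soma$z_step_um > 0, "soma: z_step_um must be > 0")
  chk(cfg$fine_focus$step_um > 0, "fine_focus: step_um must be > 0")
  chk(cfg$fine_focus$log_sigma > 0, "fine_focus: log_sigma must be > 0")
  chk(cfg$laser$focus_offset_z >= 0, "laser: focus_offset_z must be >= 0")
  for (s in names(cfg$durations))
    chk(all(cfg$durations[[s]] > 0), paste0("durations: ", s, " must be > 0"))
  chk(cfg$pipeline %in% c("event", "imaging"), "pipeline must be event/imaging")
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  class(cfg) <- "run_config"
  cfg
}

#' Load / save a run configuration as JSON
#'
#' @param path JSON file path.
#' @return `load_config` returns a validated `run_config`;
#'   `save_config` returns `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!is.null(raw$phantom$p_reject)) raw$phantom$p_reject <- unlist(raw$phantom$p_reject)
  for (s in names(raw$durations)) raw$durations[[s]] <- unlist(raw$durations[[s]])
  do.call(run_config, raw)
}

#' @rdname load_config
#' @param cfg a `run_config`.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(named_vectors_to_lists(unclass(cfg)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# JSON arrays drop R names; promote named atomic vectors to objects so
# configuration and ground truth round-trip losslessly
named_vectors_to_lists <- function(x) {
  if (is.list(x)) return(lapply(x, named_vectors_to_lists))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

# ---- constructors for sub-configs from the plain tree ----

cfg_optics <- function(cfg) do.call(optics_config, cfg$optics)
cfg_render <- function(cfg) do.call(render_params, cfg$render)
cfg_phantom_params <- function(cfg) {
  p <- cfg$phantom
  p$p_reject <- unlist(p$p_reject)
  do.call(phantom_params, p)
}
cfg_locator <- function(cfg) {
  l <- cfg$locator
  do.call(locator_config, l[setdiff(names(l), "trap_extent_um")])
}
cfg_soma <- function(cfg) do.call(soma_config, cfg$soma)
cfg_verifier <- function(cfg) do.call(verifier_config, cfg$verifier)
cfg_control <- function(cfg) do.call(control_config, cfg$control)
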