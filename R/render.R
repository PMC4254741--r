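#' Sensor / illumination parameters for rendering
#'
#' Photon shot noise is modelled as Poisson counts at an effective gain
#' (`counts = gain * Poisson(I / gain)`) with additive Gaussian read noise,
#' on top of a constant illumination background per channel.
#'
#' @param fluor_background mean fluorescence background, counts.
#' @param bf_background bright-field illumination level, counts.
#' @param bf_worm_attenuation fractional attenuation of light under the worm
#'   body (worm renders dark on bright).
#' @param photon_gain camera counts per photoelectron.
#' @param read_noise_sd Gaussian read noise, counts.
#' @param vignette_strength fractional corner fall-off of the bright-field
#'   illumination (static, present in baseline and snapshot alike).
#' @return A `render_params` list.
#' @export
render_params <- function(fluor_background = 40,
                          bf_background = 1000,
                          bf_worm_attenuation = 0.45,
                          photon_gain = 4,
                          read_noise_sd = 8,
                          vignette_strength = 0.15) {
  structure(as.list(environment()), class = "render_params")
}

#' Construct a camera frame
#' @param raster numeric matrix (rows = y, cols = x; pixel (1,1) top-left).
#' @param magnification_name,pixel_size,z_position,channel metadata.
#' @return A `camera_frame`.
#' @export
camera_frame <- function(raster, magnification_name, pixel_size, z_position,
                         channel = c("fluorescence", "brightfield")) {
  channel <- match.arg(channel)
  stopifnot(is.matrix(raster), all(raster >= 0))
  structure(list(raster = raster, magnification_name = magnification_name,
                 pixel_size = pixel_size, z_position = z_position,
                 channel = channel), class = "camera_frame")
}

#' @export
print.camera_frame <- function(x, ...) {
  cat(sprintf("<camera_frame> %s %d x %d px @ %s (%.4g um/px), z = %.2f um\n",
              x$channel, nrow(x$raster), ncol(x$raster), x$magnification_name,
              x$pixel_size, x$z_position))
  invisible(x)
}

# world coordinates seen by each pixel row/col given the rig state;
# a feature at world w appears at pixel center + (w + stage + piezo)/px
frame_world_grid <- function(rig) {
  opt <- rig$optics
  px <- pixel_size_um(opt, rig$objective)
  nr <- opt$sensor_height_px
  nc <- opt$sensor_width_px
  sx <- rig$stage$position["x"] + rig$piezo$position["x"]
  sy <- rig$stage$position["y"] + rig$piezo$position["y"]
  list(px = px, nr = nr, nc = nc,
       xw = (seq_len(nc) - (nc + 1) / 2) * px - sx,
       yw = (seq_len(nr) - (nr + 1) / 2) * px - sy,
       zf = unname(rig$stage$position["z"] + rig$piezo$position["z"]))
}

# defocus-dependent Gaussian blur sigma (um) at axial distance dz from focus
blur_sigma_um <- function(optics, dz) {
  optics$base_blur_sigma + optics$defocus_blur_scale * abs(dz)
}

add_sensor_noise <- function(img, rp) {
  n <- length(img)
  shot <- rp$photon_gain * rpois(n, pmax(img, 0) / rp$photon_gain)
  out <- shot + rnorm(n, 0, rp$read_noise_sd)
  matrix(pmax(out, 0), nrow = nrow(img))
}

# per-pixel min distance (um) to a 3-D polyline projected to xy, with the
# path z interpolated at the closest arclength; also returns arclength
grid_polyline_dist <- function(xw, yw, path) {
  nr <- length(yw); nc <- length(xw)
  px <- rep(xw, each = nr)
  py <- rep(yw, times = nc)
  res <- polyline_dist_cpp(px, py, path[, c("x", "y"), drop = FALSE])
  seg <- diff(path[, "x"])^2 + diff(path[, "y"])^2
  cum <- c(0, cumsum(sqrt(seg)))
  zat <- if (nrow(path) > 1)
    stats::approx(cum, path[, "z"], xout = res$arclength, rule = 2)$y
  else rep(path[1, "z"], length(res$dist))
  list(dist = matrix(res$dist, nr, nc),
       arclength = matrix(res$arclength, nr, nc),
       z = matrix(zat, nr, nc),
       total_length = cum[length(cum)])
}

#' Render a camera frame of a worm phantom through the virtual microscope
#'
#' Bright field renders the worm body dark against the illuminated chamber
#' background (with a static vignette shared by baseline images).
#' Fluorescence renders somas and axons as Gaussian profiles whose width
#' grows with defocus, `sigma(dz) = sigma0 + defocus_blur_scale * |dz|`,
#' conserving integrated flux so that defocused features are dimmer as well
#' as wider. A severed axon renders with a gap around `severed_at`.
#' Poisson-Gaussian sensor noise is added unless `noise = FALSE`.
#'
#' @param phantom a [make_phantom()] result, or `NULL` for an empty scene
#'   (baseline image).
#' @param rig a [rig_state()]; the active objective, stage and piezo set the
#'   viewed field and focal plane.
#' @param channel `"fluorescence"` or `"brightfield"`.
#' @param render a [render_params()].
#' @param noise logical; add sensor noise (uses the current RNG stream).
#' @param gap_half_um rendered half-width of the ablation gap, um.
#' @return A [camera_frame()].
#' @export
render_frame <- function(phantom, rig, channel = c("fluorescence", "brightfield"),
                         render = render_params(), noise = TRUE,
                         gap_half_um = 1.2) {
  channel <- match.arg(channel)
  g <- frame_world_grid(rig)
  opt <- rig$optics

  if (channel == "brightfield") {
    # static illumination profile (radially symmetric vignette)
    rr <- sqrt(outer((seq_len(g$nr) - (g$nr + 1) / 2)^2, rep(1, g$nc)) +
               outer(rep(1, g$nr), (seq_len(g$nc) - (g$nc + 1) / 2)^2))
    rmax <- sqrt(((g$nr - 1) / 2)^2 + ((g$nc - 1) / 2)^2)
    img <- render$bf_background * (1 - render$vignette_strength * (rr / rmax)^2)
    if (!is.null(phantom)) {
      bd <- grid_polyline_dist(g$xw, g$yw, cbind(phantom$body_spline, z = 0))
      # soft-edged occupancy: ~1 inside the body, ->0 over ~3 um outside
      occ <- 1 / (1 + exp((bd$dist - phantom$half_width) / 1.5))
      img <- img * (1 - render$bf_worm_attenuation * occ)
    }
  } else {
    img <- matrix(render$fluor_background, g$nr, g$nc)
    if (!is.null(phantom)) {
      for (s in phantom$somas) {
        if (s$peak_intensity <= 0) next
        sig_shape <- s$radius / 2
        sig_b <- blur_sigma_um(opt, g$zf - s$center["z"])
        sig <- sqrt(sig_shape^2 + sig_b^2)
        amp <- s$peak_intensity * sig_shape^2 / sig^2
        gx <- exp(-(g$xw - s$center["x"])^2 / (2 * sig^2))
        gy <- exp(-(g$yw - s$center["y"])^2 / (2 * sig^2))
        img <- img + amp * outer(gy, gx)
      }
      for (a in phantom$axons) {
        if (a$intensity <= 0) next
        pd <- grid_polyline_dist(g$xw, g$yw, a$path)
        sig_ax <- a$width / 2
        sig_b <- blur_sigma_um(opt, g$zf - pd$z)
        sig <- sqrt(sig_ax^2 + sig_b^2)
        # quadratic falloff: defocused light is lost axially out of the
        # collection plane, so both the peak and the in-plane integral drop
        # away from focus (keeps the mean-intensity axon-focus metric unimodal)
        amp <- a$intensity * sig_ax^2 / sig^2
        contrib <- amp * exp(-pd$dist^2 / (2 * sig^2))
        if (!is.na(a$severed_at))
          contrib[abs(pd$arclength - a$severed_at) <= gap_half_um] <- 0
        img <- img + contrib
      }
    }
  }

  if (noise) img <- add_sensor_noise(img, render)
  camera_frame(img, rig$objective, g$px, g$zf, channel)
}

#' Ablation outcome record
#' @keywords internal
ablation_outcome <- function(fired, hit, lateral_error, axial_offset,
                             pulses, pulse_energy) {
  if (hit && !fired) stop("invalid outcome: hit implies fired")
  structure(list(fired = fired, hit = hit, lateral_error = lateral_error,
                 axial_offset = axial_offset, pulses = pulses,
                 pulse_energy = pulse_energy), class = "ablation_outcome")
}

#' Fire the ablation laser at a world-coordinate target
#'
#' The cut succeeds iff (a) the lateral distance from the target to the
#' nearest axon centerline is at most `hit_tolerance` -- half of the 620 nm
#' 1/e^2 focal spot, so the axon is cut with the centre of the beam -- and
#' (b) the calibrated laser z-offset places the beam waist 0.5-0.9 um below
#' the visible focal plane. On a hit the axon's `severed_at` is set at the
#' closest arclength, so subsequent renders show the gap.
#'
#' @param phantom a [make_phantom()] result.
#' @param rig a [rig_state()] (supplies `laser_focus_offset_z`).
#' @param target `(x, y)` world coordinates of the focal spot, um.
#' @param pulses number of pulses in the train.
#' @param energy_nJ pulse energy, nJ.
#' @param hit_tolerance lateral hit radius, um.
#' @return A list with `outcome` (an `ablation_outcome`) and the possibly
#'   modified `phantom`.
#' @export
fire_ablation <- function(phantom, rig, target, pulses = 300, energy_nJ = 4,
                          hit_tolerance = 0.31) {
  stopifnot(length(target) == 2)
  best <- list(dist = Inf, k = NA_integer_, arc = NA_real_)
  for (k in seq_along(phantom$axons)) {
    a <- phantom$axons[[k]]
    res <- polyline_dist_cpp(target[1], target[2],
                             a$path[, c("x", "y"), drop = FALSE])
    if (res$dist[1] < best$dist)
      best <- list(dist = res$dist[1], k = k, arc = res$arclength[1])
  }
  dz <- rig$laser_focus_offset_z
  hit <- is.finite(best$dist) && best$dist <= hit_tolerance &&
    dz >= 0.5 && dz <= 0.9
  if (hit) phantom$axons[[best$k]]$severed_at <- best$arc
  list(outcome = ablation_outcome(fired = TRUE, hit = hit,
                                  lateral_error = unname(best$dist),
                                  axial_offset = dz,
                                  pulses = pulses, pulse_energy = energy_nJ),
       phantom = phantom)
}
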