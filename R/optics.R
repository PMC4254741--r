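#' Optics configuration for the virtual microscope
#'
#' Describes the camera sensor and the available objectives. Defaults follow a
#' CCD with 1392 x 1040 pixels of 6.45 um pitch behind a 5x/0.16 NA air
#' objective (worm localization) and a 63x/1.4 NA oil-immersion objective
#' (soma and axon work). Object-plane pixel size is `camera_pixel_pitch /
#' magnification`, i.e. 1.29 um at 5x and ~0.102 um at 63x.
#'
#' @param sensor_width_px,sensor_height_px sensor dimensions in pixels
#'   (width = columns, height = rows).
#' @param camera_pixel_pitch physical pixel pitch on the sensor, um.
#' @param magnifications list of objectives, each a list with `name`,
#'   `magnification` and `numerical_aperture`.
#' @param emission_wavelength fluorescence emission wavelength, nm.
#' @param defocus_blur_scale Gaussian-sigma growth of the rendered blur per um
#'   of defocus (um of sigma per um of |dz|).
#' @param base_blur_sigma in-focus blur sigma, um (finite optical resolution).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(sensor_width_px = 1392L,
                          sensor_height_px = 1040L,
                          camera_pixel_pitch = 6.45,
                          magnifications = list(
                            list(name = "5x", magnification = 5, numerical_aperture = 0.16),
                            list(name = "63x", magnification = 63, numerical_aperture = 1.4)
                          ),
                          emission_wavelength = 500,
                          defocus_blur_scale = 1.5,
                          base_blur_sigma = 0.15) {
  stopifnot(sensor_width_px > 0, sensor_height_px > 0, camera_pixel_pitch > 0,
            defocus_blur_scale >= 0, base_blur_sigma >= 0)
  names(magnifications) <- vapply(magnifications, `[[`, "", "name")
  for (m in magnifications) {
    if (!is.numeric(m$magnification) || m$magnification <= 0)
      stop("magnification must be strictly positive")
  }
  structure(list(
    sensor_width_px = as.integer(sensor_width_px),
    sensor_height_px = as.integer(sensor_height_px),
    camera_pixel_pitch = camera_pixel_pitch,
    magnifications = magnifications,
    emission_wavelength = emission_wavelength,
    defocus_blur_scale = defocus_blur_scale,
    base_blur_sigma = base_blur_sigma
  ), class = "optics_config")
}

#' Object-plane pixel size for a configured objective
#'
#' @param optics an [optics_config()].
#' @param magnification_name objective name, e.g. `"63x"`.
#' @return Pixel size in um per pixel (6.45/63 = 0.102... um at 63x).
#' @export
pixel_size_um <- function(optics, magnification_name) {
  m <- optics$magnifications[[magnification_name]]
  if (is.null(m)) stop("unknown magnification: ", magnification_name)
  optics$camera_pixel_pitch / m$magnification
}

#' Lateral optical resolution of an objective
#'
#' Uses the incoherent-illumination estimate `0.6 * lambda / NA`, which gives
#' 214 nm at 500 nm emission with NA 1.4.
#'
#' @inheritParams pixel_size_um
#' @param wavelength_nm wavelength in nm; defaults to the configured emission.
#' @return Resolution in nm.
#' @export
optical_resolution_nm <- function(optics, magnification_name,
                                  wavelength_nm = optics$emission_wavelength) {
  m <- optics$magnifications[[magnification_name]]
  if (is.null(m)) stop("unknown magnification: ", magnification_name)
  0.6 * wavelength_nm / m$numerical_aperture
}

#' Field of view of an objective in object-plane um
#'
#' @inheritParams pixel_size_um
#' @return Named vector `c(width_um, height_um)`.
#' @export
field_of_view_um <- function(optics, magnification_name) {
  px <- pixel_size_um(optics, magnification_name)
  c(width_um = optics$sensor_width_px * px,
    height_um = optics$sensor_height_px * px)
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf("<optics_config> sensor %d x %d px, pitch %.2f um\n",
              x$sensor_width_px, x$sensor_height_px, x$camera_pixel_pitch))
  for (m in x$magnifications) {
    cat(sprintf("  %-4s mag %g, NA %g, pixel %.4g um, FOV %.3g x %.3g um\n",
                m$name, m$magnification, m$numerical_aperture,
                x$camera_pixel_pitch / m$magnification,
                x$sensor_width_px * x$camera_pixel_pitch / m$magnification,
                x$sensor_height_px * x$camera_pixel_pitch / m$magnification))
  }
  invisible(x)
}
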