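#' Step 1 configuration: worm localization in the bright-field trap view
#'
#' @param min_particle_area particle-filter cutoff: connected components
#'   smaller than this many pixels are discarded as noise (default 300).
#' @param edge_margin_frac rejection margin as a fraction of each ROI
#'   dimension: a centroid closer than this to the ROI boundary flags the
#'   trap as unusable ("near the edge") and the worm is flushed.
#' @param threshold fixed threshold override; `NULL` (default) uses Otsu's
#'   method on the ROI histogram.
#' @param connectivity component connectivity (8 by default).
#' @return A `locator_config` list.
#' @export
locator_config <- function(min_particle_area = 300, edge_margin_frac = 0.05,
                           threshold = NULL, connectivity = 8) {
  stopifnot(min_particle_area >= 0, edge_margin_frac >= 0, edge_margin_frac < 0.5)
  structure(list(min_particle_area = min_particle_area,
                 edge_margin_frac = edge_margin_frac,
                 threshold = threshold, connectivity = connectivity),
            class = "locator_config")
}

#' Absolute background subtraction
#'
#' Subtracts the worm-free baseline image (captured with the trap membrane
#' deflected) from the snapshot of the trapped worm, leaving only the worm in
#' the difference. The absolute difference is used: the worm appears dark on
#' a bright background, and |frame - baseline| makes the sign convention
#' irrelevant.
#'
#' @param frame,baseline [camera_frame()]s or matrices of equal dimensions.
#' @return Numeric difference matrix.
#' @export
subtract_background <- function(frame, baseline) {
  f <- frame_raster(frame); b <- frame_raster(baseline)
  if (!all(dim(f) == dim(b))) stop("frame/baseline dimension mismatch")
  if (inherits(frame, "camera_frame") && inherits(baseline, "camera_frame") &&
      !identical(frame$magnification_name, baseline$magnification_name))
    stop("frame/baseline magnification mismatch")
  abs(f - b)
}

#' Threshold and particle-filter the difference image inside the trap ROI
#'
#' Applies an intensity threshold (Otsu on the ROI histogram unless a fixed
#' value is configured) inside the region of interest defined by the
#' trapping-area perimeter, then removes all connected components spanning
#' fewer than `min_particle_area` pixels. The mask is zero outside the ROI.
#'
#' @param diff difference raster from [subtract_background()].
#' @param roi `(row0, col0, rows, cols)`, 0-based half-open.
#' @param config a [locator_config()].
#' @return Logical mask with the dimensions of `diff`.
#' @export
segment_worm <- function(diff, roi, config = locator_config()) {
  sub <- crop_roi(diff, roi)  # validates the roi
  thr <- if (is.null(config$threshold)) {
    # Otsu always splits the histogram somewhere, even for a pure-noise
    # difference; a robust noise floor keeps an empty trap empty
    max(otsu_threshold(sub), median(sub) + 3 * mad(sub))
  } else config$threshold
  m <- sub > thr
  lab <- label_components(m, config$connectivity)
  if (max(lab) > 0) {
    area <- tabulate(lab[lab > 0], max(lab))
    keep <- which(area >= config$min_particle_area)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  mask <- matrix(FALSE, nrow(diff), ncol(diff))
  mask[(roi[1] + 1):(roi[1] + roi[3]), (roi[2] + 1):(roi[2] + roi[4])] <- m
  mask
}

#' Step 1: locate the trapped worm and decide accept / flush
#'
#' Runs background subtraction and segmentation, computes the area centroid
#' of the union of surviving components, and classifies the result:
#' `no_worm` if the mask is empty, `reject_near_edge` if the centroid falls
#' within `edge_margin_frac` of the ROI boundary, otherwise `accepted`.
#' For accepted worms the stage translation that centres the centroid in the
#' field of view is reported (`stage_move_um`, to be applied with
#' [move_stage()]).
#'
#' @param frame,baseline bright-field [camera_frame()]s (worm / worm-free).
#' @param roi trap region `(row0, col0, rows, cols)`, 0-based half-open.
#' @param config a [locator_config()].
#' @return A `worm_location` with `status`, sub-pixel `centroid_px`
#'   (row, col), `centroid_um` (x, y relative to frame centre),
#'   `mask_area_px` and `stage_move_um`.
#' @export
locate_worm <- function(frame, baseline, roi, config = locator_config()) {
  d <- subtract_background(frame, baseline)
  mask <- segment_worm(d, roi, config)
  px <- if (inherits(frame, "camera_frame")) frame$pixel_size else 1
  res <- list(centroid_px = c(row = NA_real_, col = NA_real_),
              centroid_um = c(x = NA_real_, y = NA_real_),
              mask_area_px = sum(mask), status = "no_worm",
              stage_move_um = c(x = 0, y = 0))
  class(res) <- "worm_location"
  if (!any(mask)) return(res)
  idx <- which(mask)
  rows <- ((idx - 1) %% nrow(mask)) + 1
  cols <- ((idx - 1) %/% nrow(mask)) + 1
  cr <- mean(rows); cc <- mean(cols)
  res$centroid_px <- c(row = cr, col = cc)
  res$centroid_um <- c(x = (cc - (ncol(mask) + 1) / 2) * px,
                       y = (cr - (nrow(mask) + 1) / 2) * px)
  mr <- config$edge_margin_frac * roi[3]
  mc <- config$edge_margin_frac * roi[4]
  near_edge <- cr < roi[1] + 1 + mr || cr > roi[1] + roi[3] - mr ||
    cc < roi[2] + 1 + mc || cc > roi[2] + roi[4] - mc
  if (near_edge) {
    res$status <- "reject_near_edge"
  } else {
    res$status <- "accepted"
    # feature at pixel p sits at viewed offset (p - centre) * px from the FOV
    # centre; translating the stage by the negative of that brings it to centre
    res$stage_move_um <- c(x = -res$centroid_um[["x"]], y = -res$centroid_um[["y"]])
  }
  res
}

#' @export
print.worm_location <- function(x, ...) {
  cat(sprintf("<worm_location> %s; centroid px (%.1f, %.1f); area %d px\n",
              x$status, x$centroid_px[1], x$centroid_px[2], x$mask_area_px))
  invisible(x)
}
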