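#' Step 3 configuration: ALM verification by straight-edge search
#'
#' @param roi_rows,roi_cols flanking ROI dimensions in pixels (150 x 200).
#' @param angle_range_deg orientations searched, degrees from the ROI
#'   horizontal (axons of a straightened, trapped worm run near-horizontal).
#' @param angle_step_deg accumulator angular resolution.
#' @param strength_threshold minimum line strength (z-score of the mean
#'   intensity along the best line against the ROI background) for an edge
#'   to count as present.
#' @param min_coverage minimum fraction of the line's length that must rise
#'   above background: a full-length requirement that rejects round blobs,
#'   which only brighten a short section of any line.
#' @return A `verifier_config` list.
#' @export
verifier_config <- function(roi_rows = 150L, roi_cols = 200L,
                            angle_range_deg = 30, angle_step_deg = 2,
                            strength_threshold = 8, min_coverage = 0.5) {
  stopifnot(roi_rows > 0, roi_cols > 0, angle_range_deg > 0,
            angle_step_deg > 0, strength_threshold > 0)
  structure(list(roi_rows = as.integer(roi_rows), roi_cols = as.integer(roi_cols),
                 angle_range_deg = angle_range_deg,
                 angle_step_deg = angle_step_deg,
                 strength_threshold = strength_threshold,
                 min_coverage = min_coverage),
            class = "verifier_config")
}

#' Flanking ROIs on the left and right of a detected soma
#'
#' Two `roi_rows x roi_cols` rectangles vertically centred on the soma,
#' abutting its bounding circle on either side, clipped to the frame. If
#' either ROI clips below 50% of its nominal area the soma is too close to
#' the frame edge for verification and a rejection condition is raised
#' (the controller flushes the worm).
#'
#' @param soma_center_px `(row, col)` soma centre.
#' @param frame_dims `(rows, cols)` of the frame.
#' @param soma_radius_px soma bounding radius in pixels.
#' @param config a [verifier_config()].
#' @return List with `left` and `right` ROIs (`(row0, col0, rows, cols)`,
#'   0-based half-open).
#' @export
flanking_rois <- function(soma_center_px, frame_dims, soma_radius_px = 25,
                          config = verifier_config()) {
  r0 <- round(soma_center_px[[1]] - 1 - config$roi_rows / 2)
  left <- c(r0, round(soma_center_px[[2]] - 1 - soma_radius_px - config$roi_cols),
            config$roi_rows, config$roi_cols)
  right <- c(r0, round(soma_center_px[[2]] - 1 + soma_radius_px),
             config$roi_rows, config$roi_cols)
  nominal <- config$roi_rows * config$roi_cols
  out <- list()
  for (side in c("left", "right")) {
    roi <- clip_roi(if (side == "left") left else right, frame_dims)
    if (is.null(roi) || roi[3] * roi[4] < 0.5 * nominal)
      stop(errorCondition(
        paste0("flanking ROI (", side, ") clips below 50% of nominal area"),
        class = c("axobot_reject", "error", "condition")))
    out[[side]] <- roi
  }
  out
}

#' Detect a straight, near-horizontal bright feature in a ROI
#'
#' A Hough-style accumulator over line orientations within
#' `+/-angle_range_deg` of horizontal: for each orientation the image is
#' sheared so candidate lines become rows, and the mean intensity of every
#' full-length line is scored against the ROI background (median, with MAD
#' noise scaling). The strongest line is reported; it is `present` when its
#' strength reaches the configured threshold *and* the intensity profile
#' along it stays above background over at least `min_coverage` of its
#' length (a round soma-like blob fails this even when bright).
#'
#' @param roi_image numeric matrix (fluorescence ROI at best focus).
#' @param config a [verifier_config()].
#' @return An `edge_evidence` list: `present`, `strength`, `angle` (degrees
#'   from horizontal), `mean_intensity_on_line`, `coverage`.
#' @export
detect_straight_edge <- function(roi_image, config = verifier_config()) {
  nr <- nrow(roi_image); nc <- ncol(roi_image)
  bg <- median(roi_image)
  noise <- max(mad(roi_image), 1e-9)
  angles <- seq(-config$angle_range_deg, config$angle_range_deg,
                by = config$angle_step_deg)
  best <- list(score = -Inf, angle = 0, intercept = NA_real_)
  for (ang in angles) {
    slope <- tan(ang * pi / 180)
    off <- round(slope * (seq_len(nc) - 1))
    # shear: line row = b + slope*col maps to accumulator bin b
    lo <- 1 - max(off); hi <- nr - min(off)
    nb <- hi - lo + 1
    acc <- numeric(nb); cnt <- numeric(nb)
    for (cc in seq_len(nc)) {
      b <- (seq_len(nr) - off[cc]) - lo + 1   # bins hit by this column
      acc[b] <- acc[b] + roi_image[, cc]
      cnt[b] <- cnt[b] + 1
    }
    full <- cnt >= 0.9 * nc   # only (nearly) full-length lines compete
    if (!any(full)) next
    mean_line <- acc[full] / cnt[full]
    k <- which.max(mean_line)
    score <- (mean_line[k] - bg) / (noise / sqrt(nc))
    if (score > best$score) {
      best <- list(score = score, angle = ang,
                   intercept = which(full)[k] + lo - 1,
                   mean_intensity = mean_line[k])
    }
  }
  coverage <- 0
  if (is.finite(best$score)) {
    slope <- tan(best$angle * pi / 180)
    cols <- seq_len(nc)
    rows <- round(best$intercept + slope * (cols - 1))
    ok <- rows >= 1 & rows <= nr
    vals <- roi_image[cbind(rows[ok], cols[ok])]
    # segment-wise coverage: a real axon lights up (nearly) the whole line,
    # a compact blob only a few consecutive segments
    nseg <- 10L
    seg <- cut(seq_along(vals), nseg, labels = FALSE)
    seg_mean <- tapply(vals, seg, mean)
    seg_n <- tapply(vals, seg, length)
    coverage <- mean(seg_mean > bg + 3 * noise / sqrt(seg_n))
  }
  present <- is.finite(best$score) &&
    best$score >= config$strength_threshold &&
    coverage >= config$min_coverage
  structure(list(present = present,
                 strength = if (is.finite(best$score)) best$score else 0,
                 angle = best$angle,
                 mean_intensity_on_line = if (is.null(best$mean_intensity)) bg else best$mean_intensity,
                 coverage = coverage),
            class = "edge_evidence")
}

#' Classify the detected soma from the two flanking edge evidences
#'
#' No straight edge on either side: the soma is not the target neuron (the
#' AVM carries no straight process in the small FOV) and the worm is
#' flushed. An edge on exactly one side identifies an ALM with the head
#' towards that side (ALM processes extend anteriorly). Edges on both sides
#' (an ALM with an additional posterior process): the brighter line marks
#' the main anterior axon, hence the head.
#'
#' @param left,right `edge_evidence` from [detect_straight_edge()].
#' @return A `neuron_id` with `classification` (`"ALM"` / `"not_target"`),
#'   `head_direction` (`"left"`, `"right"`, `"unknown"`) and both evidences.
#' @export
classify_neuron <- function(left, right) {
  if (!left$present && !right$present) {
    cls <- "not_target"; head <- "unknown"
  } else if (left$present && !right$present) {
    cls <- "ALM"; head <- "left"
  } else if (!left$present && right$present) {
    cls <- "ALM"; head <- "right"
  } else {
    cls <- "ALM"
    head <- if (right$mean_intensity_on_line > left$mean_intensity_on_line)
      "right" else "left"
  }
  structure(list(classification = cls, head_direction = head,
                 evidence = list(left = left, right = right)),
            class = "neuron_id")
}

#' @export
print.neuron_id <- function(x, ...) {
  cat(sprintf("<neuron_id> %s, head %s (strength L %.1f / R %.1f)\n",
              x$classification, x$head_direction,
              x$evidence$left$strength, x$evidence$right$strength))
  invisible(x)
}

#' Step 3: verify the neuron in a frame around a soma detection
#'
#' Convenience wrapper: builds the flanking ROIs, runs the straight-edge
#' detector on both, and classifies.
#'
#' @param frame fluorescence [camera_frame()] at best focus.
#' @param det a `soma_detection`.
#' @param config a [verifier_config()].
#' @return A `neuron_id`.
#' @export
verify_neuron <- function(frame, det, config = verifier_config()) {
  r <- frame_raster(frame)
  px <- if (inherits(frame, "camera_frame")) frame$pixel_size else 1
  rad_px <- max(det$equivalent_diameter / 2 / px, 10) + 5
  rois <- flanking_rois(det$center_px, dim(r), soma_radius_px = rad_px,
                        config = config)
  classify_neuron(detect_straight_edge(crop_roi(r, rois$left), config),
                  detect_straight_edge(crop_roi(r, rois$right), config))
}
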