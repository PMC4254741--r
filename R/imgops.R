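#' Crop a rectangular region of interest from a raster
#'
#' ROIs are given as `(row0, col0, rows, cols)`, 0-based, half-open -- the
#' same convention used in configuration files.
#'
#' @param image numeric matrix.
#' @param roi integer vector `(row0, col0, rows, cols)`.
#' @return The cropped matrix.
#' @export
crop_roi <- function(image, roi) {
  stopifnot(length(roi) == 4)
  r0 <- roi[1]; c0 <- roi[2]; nr <- roi[3]; nc <- roi[4]
  if (nr <= 0 || nc <= 0) stop("empty roi")
  if (r0 < 0 || c0 < 0 || r0 + nr > nrow(image) || c0 + nc > ncol(image))
    stop("roi outside frame: (", paste(roi, collapse = ","), ") vs ",
         nrow(image), " x ", ncol(image))
  image[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc), drop = FALSE]
}

# clip an roi to the frame; returns NULL if nothing remains
clip_roi <- function(roi, dims) {
  r0 <- max(roi[1], 0); c0 <- max(roi[2], 0)
  r1 <- min(roi[1] + roi[3], dims[1]); c1 <- min(roi[2] + roi[4], dims[2])
  if (r1 <= r0 || c1 <= c0) return(NULL)
  c(r0, c0, r1 - r0, c1 - c0)
}

#' Otsu's threshold
#'
#' Maximizes between-class variance over a 256-bin histogram of the input.
#'
#' @param x numeric vector or matrix of intensities.
#' @param nbins number of histogram bins.
#' @return Threshold on the intensity scale of `x` (pixels `> threshold` are
#'   foreground).
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of labels, 0 for background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  label_components_cpp(mask, as.integer(connectivity))
}

#' Per-component measurements
#'
#' Computes area, area centroid, equivalent diameter, an unbiased perimeter
#' estimate and circularity (`4 pi A / P^2`) for every labelled component.
#' The perimeter counts exposed pixel edges scaled by `pi/4`, which is exact
#' in expectation for isotropically oriented smooth boundaries (a digital
#' circle of radius R exposes ~8R edges, giving P ~ 2 pi R).
#'
#' @param labels integer label matrix from [label_components()].
#' @param intensity optional raster of the same size for per-component mean
#'   intensity.
#' @return A data.frame with one row per component: `label`, `area`,
#'   `centroid_row`, `centroid_col`, `equiv_diameter_px`, `perimeter_px`,
#'   `circularity`, and `mean_intensity` when `intensity` is given.
#' @export
component_stats <- function(labels, intensity = NULL) {
  n <- max(labels)
  if (n == 0)
    return(data.frame(label = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      equiv_diameter_px = numeric(), perimeter_px = numeric(),
                      circularity = numeric(), mean_intensity = numeric()))
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1) %% nrow(labels)) + 1
  cols <- ((idx - 1) %/% nrow(labels)) + 1
  area <- tabulate(lab, n)
  crow <- tapply(rows, lab, mean)
  ccol <- tapply(cols, lab, mean)

  # convex-hull perimeter of the pixel centres, plus pi to account for the
  # half-pixel border (exact for a digital disc: 2*pi*(R - 1/2) + pi = 2*pi*R);
  # robust to noise-ragged boundaries, still penalizes elongated shapes
  perim <- vapply(seq_len(n), function(l) {
    pr <- rows[lab == l]; pc <- cols[lab == l]
    if (length(pr) <= 2) return(2 * sqrt(length(pr) / pi) * pi)
    h <- grDevices::chull(pc, pr)
    hx <- pc[h]; hy <- pr[h]
    sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2)) + pi
  }, numeric(1))
  circ <- pmin(4 * pi * area / perim^2, 1)
  out <- data.frame(label = seq_len(n), area = area,
                    centroid_row = as.numeric(crow), centroid_col = as.numeric(ccol),
                    equiv_diameter_px = 2 * sqrt(area / pi),
                    perimeter_px = perim, circularity = circ)
  if (!is.null(intensity))
    out$mean_intensity <- as.numeric(tapply(intensity[idx], lab, mean))
  out
}
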