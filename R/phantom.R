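#' Distribution settings for synthetic worm phantoms
#'
#' The phantom emulates a young/mid-L4 hermaphrodite pressed against the
#' trapping-area sieve: a gently curved body ~600 um long with GFP-labelled
#' touch neurons. The two ALM somas sit near the worm centroid on either
#' side of the body, a few um to ~20 um above the cover glass, with ~300
#' nm-wide anterior processes running towards the head; the AVM soma carries
#' no straight process within the small field of view.
#'
#' `p_reject` gives the probabilities (as fractions of all processed worms)
#' with which a phantom is drawn carrying a degenerate feature that causes
#' the automation to flush it at the corresponding step:
#' * `trap`: folded or trapped far off-centre (worm centroid near the ROI edge),
#' * `soma`: no detectable fluorescent soma (failed GFP expression / soma
#'   missed between coarse steps),
#' * `axon`: the bright soma in the field of view is the AVM, or the ALM
#'   axon signal is too weak for edge verification,
#' * `ablation`: the axon lies beyond the piezo travel at the target site so
#'   the alignment loop cannot converge.
#'
#' Defaults (0.10, 0.10, 0.091, 0.035) reproduce the observed per-step
#' attrition of the automated platform, leaving a 67.4% expected success rate.
#'
#' @param body_length_um,body_half_width_um ranges (min, max), um.
#' @param body_wave_amp_um range of body-curvature amplitude, um.
#' @param centroid_offset_um max |offset| of the trapped centroid from the
#'   trap centre on each axis, um.
#' @param soma_radius_um soma radius range, um (diameters 3-5 um, inside the
#'   2-6 um detection gate).
#' @param soma_depth_um depth range of the glass-proximal ALM soma, um.
#' @param soma_peak_intensity fluorescence peak of an in-focus soma, camera counts.
#' @param axon_width_um axon diameter, um (~0.3).
#' @param axon_intensity fluorescence amplitude of an in-focus axon, counts.
#' @param axon_length_um anterior process length, um.
#' @param p_posterior_process probability of an extra (dimmer) posterior process.
#' @param p_reject named degenerate-case probabilities, see Details.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(body_length_um = c(550, 650),
                           body_half_width_um = c(12, 18),
                           body_wave_amp_um = c(5, 15),
                           centroid_offset_um = 30,
                           soma_radius_um = c(1.5, 2.5),
                           soma_depth_um = c(4, 10),
                           soma_peak_intensity = 3000,
                           axon_width_um = 0.3,
                           axon_intensity = 500,
                           axon_length_um = 200,
                           p_posterior_process = 0.2,
                           p_reject = c(trap = 0.10, soma = 0.10,
                                        axon = 0.091, ablation = 0.035)) {
  rng <- function(r, what) {
    if (length(r) != 2 || r[1] > r[2]) stop("invalid range for ", what, " (min > max)")
    r
  }
  p_reject <- p_reject[c("trap", "soma", "axon", "ablation")]
  if (anyNA(p_reject)) stop("p_reject must name trap, soma, axon, ablation")
  if (any(p_reject < 0) || sum(p_reject) > 1)
    stop("p_reject entries must be >= 0 and sum to <= 1")
  structure(list(
    body_length_um = rng(body_length_um, "body_length_um"),
    body_half_width_um = rng(body_half_width_um, "body_half_width_um"),
    body_wave_amp_um = rng(body_wave_amp_um, "body_wave_amp_um"),
    centroid_offset_um = centroid_offset_um,
    soma_radius_um = rng(soma_radius_um, "soma_radius_um"),
    soma_depth_um = rng(soma_depth_um, "soma_depth_um"),
    soma_peak_intensity = soma_peak_intensity,
    axon_width_um = axon_width_um,
    axon_intensity = axon_intensity,
    axon_length_um = axon_length_um,
    p_posterior_process = p_posterior_process,
    p_reject = p_reject
  ), class = "phantom_params")
}

#' Generate a synthetic worm phantom
#'
#' Draws one ground-truth worm (body polyline, ALML/ALMR/AVM somas, axon
#' paths, orientation, degenerate-case flags) from [phantom_params()].
#' Deterministic for a fixed seed. Coordinates are object-plane um with the
#' origin at the trapping-area centre; x runs along the worm (head direction
#' is `c(-1, 0)` or `c(1, 0)`), y across it, z into the worm from the cover
#' glass.
#'
#' @param params a [phantom_params()].
#' @param seed integer seed; if `NULL` the current RNG stream is used.
#' @return A `worm_phantom` with fields `body_spline` (n x 2 matrix),
#'   `half_width`, `centroid`, `orientation`, `somas`, `axons`, `folded`,
#'   and `degenerate` (one of `"none"`, `"trap"`, `"soma"`, `"axon"`,
#'   `"ablation"`).
#' @export
make_phantom <- function(params = phantom_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ru <- function(r) runif(1, r[1], r[2])

  # one categorical draw decides the degenerate class
  u <- runif(1)
  cum <- cumsum(params$p_reject)
  degenerate <- if (u < cum[1]) "trap" else if (u < cum[2]) "soma" else
    if (u < cum[3]) "axon" else if (u < cum[4]) "ablation" else "none"

  head_sign <- sample(c(-1, 1), 1)
  L <- ru(params$body_length_um)
  hw <- ru(params$body_half_width_um)
  amp <- ru(params$body_wave_amp_um)
  cx <- runif(1, -params$centroid_offset_um, params$centroid_offset_um)
  cy <- runif(1, -params$centroid_offset_um, params$centroid_offset_um)

  folded <- FALSE
  if (degenerate == "trap") {
    folded <- runif(1) < 0.5
    # park the worm so only a thin sliver remains inside the trap ROI
    # (default trap extent +/-300 um in x): its visible centroid then falls
    # inside the edge-rejection margin
    half_span <- if (folded) L / 4 else L / 2
    cx <- sign(runif(1) - 0.5) * (300 + half_span - 25)
    cy <- runif(1, -20, 20)
  }

  if (folded) {
    body <- cbind(x = cx + c(-L/4, 0, L/4, 0, -L/4),
                  y = cy + c(-60, -30, 0, 30, 60))
  } else {
    xs <- seq(-L/2, L/2, length.out = 15)
    body <- cbind(x = cx + xs, y = cy + amp * sin(2 * pi * xs / (0.9 * L) + runif(1, 0, 2 * pi)))
  }

  soma_int <- params$soma_peak_intensity
  axon_int <- params$axon_intensity
  avm_only <- FALSE
  weak_axon <- FALSE
  if (degenerate == "soma") soma_int <- 0
  if (degenerate == "axon") {
    if (runif(1) < 0.5) avm_only <- TRUE else weak_axon <- TRUE
  }
  if (weak_axon) axon_int <- 0.05 * params$axon_intensity

  r1 <- ru(params$soma_radius_um)
  r2 <- ru(params$soma_radius_um)
  z1 <- ru(params$soma_depth_um)
  z2 <- z1 + runif(1, 8, 15)
  sx <- cx + runif(1, -10, 10)
  side <- sample(c(-1, 1), 1)
  somas <- list(
    list(label = "ALML", center = c(x = sx, y = cy + side * runif(1, 5, 9), z = z1),
         radius = r1, peak_intensity = if (avm_only) 0 else soma_int),
    list(label = "ALMR", center = c(x = sx + runif(1, -5, 5),
                                    y = cy - side * runif(1, 5, 9), z = z2),
         radius = r2, peak_intensity = if (avm_only) 0 else soma_int),
    # when the AVM is the only bright soma it must actually appear in the
    # small FOV centred on the worm centroid for the cycle to reach Step 3
    list(label = "AVM", center = c(x = cx + head_sign *
                                     (if (avm_only) runif(1, 5, 15) else runif(1, 15, 40)),
                                   y = cy + runif(1, -4, 4),
                                   z = if (avm_only) ru(params$soma_depth_um) else z1 + runif(1, 3, 6)),
         radius = ru(params$soma_radius_um), peak_intensity = soma_int)
  )

  make_axon_path <- function(soma, unreachable = FALSE) {
    n <- 9L
    step <- params$axon_length_um / (n - 1)
    xs <- soma$center["x"] + head_sign * step * (0:(n - 1))
    dev <- cumsum(c(0, pmin(pmax(rnorm(n - 1, 0, 0.3), -0.6), 0.6)))
    dev <- pmin(pmax(dev, -2), 2)
    if (unreachable) dev[xs * head_sign >= soma$center["x"] * head_sign + 30] <- 12
    ys <- soma$center["y"] + dev
    zs <- soma$center["z"] + seq(0, runif(1, -0.3, 0.3), length.out = n)
    cbind(x = unname(xs), y = unname(ys), z = unname(zs))
  }

  axons <- list()
  if (!avm_only) {
    for (k in 1:2) {
      s <- somas[[k]]
      axons[[length(axons) + 1]] <- list(
        label = paste0(s$label, "_anterior"),
        path = make_axon_path(s, unreachable = (degenerate == "ablation" && k == 1)),
        width = params$axon_width_um,
        intensity = if (s$peak_intensity > 0) axon_int else 0,
        severed_at = NA_real_)
      if (runif(1) < params$p_posterior_process) {
        sp <- s
        post <- make_axon_path(sp)
        post[, "x"] <- 2 * s$center["x"] - post[, "x"]  # mirror towards tail
        post <- post[seq_len(4), , drop = FALSE]        # shorter process
        axons[[length(axons) + 1]] <- list(
          label = paste0(s$label, "_posterior"), path = post,
          width = params$axon_width_um,
          intensity = 0.5 * (if (s$peak_intensity > 0) axon_int else 0),
          severed_at = NA_real_)
      }
    }
  }

  structure(list(
    body_spline = body, half_width = hw,
    centroid = c(x = cx, y = cy),
    orientation = c(head_sign, 0),
    somas = somas, axons = axons,
    folded = folded, degenerate = degenerate
  ), class = "worm_phantom")
}

#' @export
print.worm_phantom <- function(x, ...) {
  cat(sprintf("<worm_phantom> centroid (%.1f, %.1f) um, head %s, %d somas, %d axon paths%s%s\n",
              x$centroid[1], x$centroid[2], if (x$orientation[1] < 0) "left" else "right",
              length(x$somas), length(x$axons),
              if (x$folded) ", folded" else "",
              if (x$degenerate != "none") paste0(", degenerate=", x$degenerate) else ""))
  invisible(x)
}

#' Serialize phantom ground truth to JSON
#' @param phantom a [make_phantom()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phantom_json <- function(phantom, path) {
  obj <- unclass(phantom)
  obj$body_spline <- apply(phantom$body_spline, 1, as.list)
  obj$axons <- lapply(obj$axons, function(a) {
    a$path <- apply(a$path, 1, as.list)
    a
  })
  obj <- named_vectors_to_lists(obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
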