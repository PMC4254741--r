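# Shared fixtures and independent oracles. Everything is generated in code;
# image work runs on a reduced sensor (same pixel pitch and magnifications,
# smaller chip) so the suite stays fast -- pixel geometry is unchanged.

fast_optics <- function(width = 640L, height = 480L) {
  optics_config(sensor_width_px = width, sensor_height_px = height)
}

fast_cfg <- function(..., width = 640L, height = 480L) {
  run_config(optics = list(sensor_width_px = width, sensor_height_px = height),
             ...)
}

clean_params <- function(...) {
  phantom_params(p_reject = c(trap = 0, soma = 0, axon = 0, ablation = 0), ...)
}

# a minimal phantom with a single straight axon and no somas, for targeting
# tests with exactly known geometry
axon_only_phantom <- function(y_um = 5, z_um = 0, intensity = 500,
                              x_range = c(-40, 40)) {
  structure(list(
    body_spline = cbind(x = x_range, y = c(0, 0)), half_width = 15,
    centroid = c(x = 0, y = 0), orientation = c(1, 0),
    somas = list(),
    axons = list(list(label = "ax",
                      path = cbind(x = x_range, y = c(y_um, y_um),
                                   z = c(z_um, z_um)),
                      width = 0.3, intensity = intensity,
                      severed_at = NA_real_)),
    folded = FALSE, degenerate = "none"), class = "worm_phantom")
}

# soma-only phantom at a configurable depth
soma_phantom <- function(z_um, radius = 2, xy = c(0, 0), peak = 3000) {
  structure(list(
    body_spline = cbind(x = c(-50, 50), y = c(0, 0)), half_width = 15,
    centroid = c(x = 0, y = 0), orientation = c(1, 0),
    somas = list(list(label = "ALML",
                      center = c(x = xy[1], y = xy[2], z = z_um),
                      radius = radius, peak_intensity = peak)),
    axons = list(), folded = FALSE, degenerate = "none"),
    class = "worm_phantom")
}

# ---- independent oracles ----

# brute-force 2-D convolution with mirror-reflected borders (nested loops)
oracle_conv2 <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kern); kc <- ncol(kern)
  hr <- (kr - 1) / 2; hc <- (kc - 1) / 2
  refl <- function(i, n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in -hr:hr) for (b in -hc:hc) {
      ii <- refl(i + a, nr); jj <- refl(j + b, nc)
      acc <- acc + img[ii, jj] * kern[hr + 1 - a, hc + 1 - b]
    }
    out[i, j] <- acc
  }
  out
}

# naive two-pass population variance
oracle_variance <- function(img) {
  m <- 0
  for (v in img) m <- m + v
  m <- m / length(img)
  s <- 0
  for (v in img) s <- s + (v - m)^2
  s / length(img)
}

# exhaustive two-sided Fisher p by enumerating all tables with the observed
# margins, using only choose()
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(c1, r1)
  prob <- vapply(ks, function(k)
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
  p_obs <- prob[ks == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# point-to-segment distance for footprint oracles (pure R)
oracle_polyline_dist <- function(px, py, verts) {
  best <- Inf
  for (k in seq_len(nrow(verts) - 1)) {
    ax <- verts[k, 1]; ay <- verts[k, 2]
    bx <- verts[k + 1, 1]; by <- verts[k + 1, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) max(0, min(1, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    best <- min(best, sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2))
  }
  best
}

# step-by-step piezo backlash hand-simulation (mirrors the stated contract,
# written independently of the implementation)
oracle_piezo_walk <- function(deltas, deadband = 0.1, step = 0.025) {
  pos <- 0; last <- 0
  for (d in deltas) {
    if (d == 0) next
    s <- sign(d)
    eff <- if (s != last) s * max(0, abs(d) - deadband) else d
    pos <- pos + round(eff / step) * step
    last <- s
  }
  pos
}
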