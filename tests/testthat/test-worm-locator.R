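roi_for <- function(optics = fast_optics(), extent = c(600, 400)) {
  px <- pixel_size_um(optics, "5x")
  rr <- round(extent[2] / px); rc <- round(extent[1] / px)
  c(floor((optics$sensor_height_px - rr) / 2),
    floor((optics$sensor_width_px - rc) / 2), rr, rc)
}

test_that("background subtraction is an absolute difference with shape checks", {
  m <- matrix(runif(100), 10)
  expect_equal(subtract_background(m, m), matrix(0, 10, 10))
  expect_equal(subtract_background(m + 3, m), matrix(3, 10, 10))
  expect_equal(subtract_background(m, m + 3), matrix(3, 10, 10))
  expect_error(subtract_background(m, matrix(0, 5, 5)), "mismatch")
})

test_that("particle filter removes blobs below 300 pixels", {
  d <- matrix(0, 200, 300)
  d[10:25, 10:25] <- 100        # 256 px: below the cutoff
  d[100:170, 100:170] <- 100    # 5041 px: survives
  mask <- segment_worm(d, roi = c(0, 0, 200, 300),
                       config = locator_config(threshold = 50))
  expect_equal(sum(mask), 71 * 71)
  expect_false(any(mask[10:25, 10:25]))

  expect_equal(sum(segment_worm(matrix(0, 50, 50), c(0, 0, 50, 50),
                                locator_config(threshold = 10))), 0)
  expect_error(segment_worm(d, c(0, 0, 0, 10)), "empty roi")
})

test_that("segmented footprint area matches the phantom geometry oracle", {
  ph <- make_phantom(clean_params(body_length_um = c(380, 380),
                                  centroid_offset_um = 5), seed = 21)
  opt <- fast_optics()
  rig <- rig_state(opt, "5x")
  set.seed(77)
  fr <- render_frame(ph, rig, "brightfield")
  bl <- render_frame(NULL, rig, "brightfield")
  roi <- roi_for(opt)
  mask <- segment_worm(subtract_background(fr, bl), roi, locator_config())
  px <- pixel_size_um(opt, "5x")
  # oracle: count ROI pixels whose world point lies within the half-width
  # of the body polyline (sampled on a stride-2 grid for speed)
  inside <- 0L
  for (r in seq(1, roi[3], by = 2)) {
    y <- (roi[1] + r - (480 + 1) / 2) * px
    for (cc in seq(1, roi[4], by = 2)) {
      x <- (roi[2] + cc - (640 + 1) / 2) * px
      if (oracle_polyline_dist(x, y, ph$body_spline) <= ph$half_width)
        inside <- inside + 1L
    }
  }
  expect_lt(abs(sum(mask) - 4 * inside) / (4 * inside), 0.15)
})

test_that("locate_worm accepts a centred worm and recovers its centroid", {
  # a worm short enough to sit fully inside the trap ROI
  ph <- make_phantom(clean_params(body_length_um = c(380, 380),
                                  body_wave_amp_um = c(6, 6),
                                  centroid_offset_um = 5), seed = 31)
  opt <- fast_optics()
  rig <- rig_state(opt, "5x")
  set.seed(7)
  fr <- render_frame(ph, rig, "brightfield")
  bl <- render_frame(NULL, rig, "brightfield")
  loc <- locate_worm(fr, bl, roi_for(opt))
  expect_identical(loc$status, "accepted")
  px <- pixel_size_um(opt, "5x")
  true_col <- (640 + 1) / 2 + ph$centroid["x"] / px
  true_row <- (480 + 1) / 2 + ph$centroid["y"] / px
  expect_lt(abs(loc$centroid_px[["col"]] - true_col), 2)
  expect_lt(abs(loc$centroid_px[["row"]] - true_row), 2)
  # the reported stage move centres the worm
  expect_equal(unname(loc$stage_move_um), -unname(loc$centroid_um),
               tolerance = 1e-9)
})

test_that("a blank difference yields no_worm; near-edge centroids are flushed", {
  opt <- fast_optics()
  rig <- rig_state(opt, "5x")
  set.seed(8)
  b1 <- render_frame(NULL, rig, "brightfield")
  b2 <- render_frame(NULL, rig, "brightfield")
  expect_identical(locate_worm(b1, b2, roi_for(opt))$status, "no_worm")

  ph <- make_phantom(phantom_params(p_reject = c(trap = 1, soma = 0,
                                                 axon = 0, ablation = 0)),
                     seed = 13)
  set.seed(9)
  fr <- render_frame(ph, rig, "brightfield")
  expect_identical(locate_worm(fr, b1, roi_for(opt))$status, "reject_near_edge")
})

test_that("centroid is translation-invariant and robust to small noise blobs", {
  d <- matrix(0, 200, 300)
  d[80:120, 100:200] <- 100
  cfg <- locator_config(threshold = 50)
  roi <- c(0, 0, 200, 300)
  base <- locate_worm(d, matrix(0, 200, 300), roi, cfg)
  shifted <- matrix(0, 200, 300)
  shifted[(80:120) + 7, (100:200) - 11] <- 100
  s <- locate_worm(shifted, matrix(0, 200, 300), roi, cfg)
  expect_equal(s$centroid_px[["row"]] - base$centroid_px[["row"]], 7, tolerance = 0.5)
  expect_equal(s$centroid_px[["col"]] - base$centroid_px[["col"]], -11, tolerance = 0.5)

  noisy <- d
  noisy[5:14, 5:14] <- 100      # 100 px blob, below min_particle_area
  noisy[180:190, 250:260] <- 100
  n <- locate_worm(noisy, matrix(0, 200, 300), roi, cfg)
  expect_equal(n$centroid_px, base$centroid_px, tolerance = 1e-9)
})
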