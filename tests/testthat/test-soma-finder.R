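test_that("uniform frames and oversized blobs yield no detection", {
  f <- camera_frame(matrix(50, 200, 200), "63x", 6.45 / 63, 0)
  expect_null(detect_circular_feature(f))
  # 10 um blob: passes threshold, fails the 2-6 um diameter gate
  big <- soma_phantom(z_um = 5, radius = 5)
  rig <- rig_state(fast_optics(), "63x"); rig$stage$position["z"] <- 5
  fr <- render_frame(big, rig, "fluorescence", noise = FALSE)
  expect_null(detect_circular_feature(fr))
})

test_that("an in-focus 4 um soma is detected at the right place and size", {
  ph <- soma_phantom(z_um = 5, radius = 2, xy = c(3, -4))
  rig <- rig_state(fast_optics(), "63x"); rig$stage$position["z"] <- 5
  set.seed(42)
  fr <- render_frame(ph, rig, "fluorescence")
  det <- detect_circular_feature(fr)
  expect_false(is.null(det))
  expect_gte(det$equivalent_diameter, 3.2)
  expect_lte(det$equivalent_diameter, 4.8)
  px <- fr$pixel_size
  expect_lt(abs(det$center_px[["col"]] - ((640 + 1) / 2 + 3 / px)), 1)
  expect_lt(abs(det$center_px[["row"]] - ((480 + 1) / 2 - 4 / px)), 1)
  expect_gte(det$circularity, 0.6)

  # detection is invariant to a global intensity gain (threshold is relative)
  f2 <- fr; f2$raster <- fr$raster * 3.7
  det2 <- detect_circular_feature(f2)
  expect_equal(det2$center_px, det$center_px)
  expect_equal(det2$equivalent_diameter, det$equivalent_diameter)
})

test_that("coarse scan finds shallow somas quickly and gives up after 10", {
  cfgs <- soma_config()
  rig <- rig_state(fast_optics(), "63x")
  set.seed(5)
  res <- coarse_focus_scan(rig, soma_phantom(z_um = 5), cfgs)
  expect_false(is.null(res$detection))
  expect_lte(res$iterations, 3)
  expect_equal(res$detection$iterations_used, res$iterations)

  # soma right at the starting plane: found on iteration 1
  set.seed(6)
  res1 <- coarse_focus_scan(rig, soma_phantom(z_um = 0.3), cfgs)
  expect_equal(res1$iterations, 1)

  # no fluorescent somas: rejection after exactly 10 frames
  pp <- phantom_params(p_reject = c(trap = 0, soma = 1, axon = 0, ablation = 0))
  set.seed(7)
  dark <- make_phantom(pp, seed = 3)
  res0 <- coarse_focus_scan(rig, dark, cfgs)
  expect_null(res0$detection)
  expect_equal(res0$iterations, 10)
})

test_that("scan depth bound: findable at 24 um, guaranteed rejection at 26 um", {
  rig <- rig_state(fast_optics(), "63x")
  set.seed(8)
  near <- coarse_focus_scan(rig, soma_phantom(z_um = 24, radius = 2.2))
  expect_false(is.null(near$detection))
  set.seed(9)
  deep <- coarse_focus_scan(rig, soma_phantom(z_um = 26, radius = 2.2))
  expect_null(deep$detection)
  expect_equal(deep$iterations, 10)
})

test_that("coarse scan accepts pre-recorded stacks", {
  ph <- soma_phantom(z_um = 5)
  zs <- seq(0, 22.5, by = 2.5)
  frames <- lapply(zs, function(z) {
    rig <- rig_state(fast_optics(192L, 160L), "63x")
    rig$stage$position["z"] <- z
    render_frame(ph, rig, "fluorescence", noise = FALSE)
  })
  res <- coarse_focus_scan(rig_state(fast_optics(192L, 160L), "63x"),
                           zstack(frames, zs))
  expect_false(is.null(res$detection))
  expect_equal(res$iterations, which.min(abs(zs - 5)))
})

test_that("center_on_laser_spot translates the soma onto the spot pixel", {
  opt <- fast_optics()
  rig <- rig_state(opt, "63x")
  px <- pixel_size_um(opt, "63x")
  spot <- c((480 + 1) / 2, (640 + 1) / 2)
  det <- structure(list(center_px = c(row = spot[1], col = spot[2] + 30),
                        equivalent_diameter = 4), class = "soma_detection")
  moved <- center_on_laser_spot(rig, det, spot)
  expect_equal(unname(moved$stage$position["x"]), -30 * px, tolerance = 0.051)
  # already on the spot: no move
  det0 <- structure(list(center_px = c(row = spot[1], col = spot[2]),
                         equivalent_diameter = 4), class = "soma_detection")
  expect_equal(center_on_laser_spot(rig, det0, spot)$stage$position,
               rig$stage$position)
  # beyond the trap extent: rejection condition
  far <- structure(list(center_px = c(row = spot[1], col = spot[2] + 2000),
                        equivalent_diameter = 4), class = "soma_detection")
  expect_error(center_on_laser_spot(rig, far, spot), class = "axobot_reject")

  # closed loop: after the move a rendered soma sits within 1 px of the spot
  ph <- soma_phantom(z_um = 5, xy = c(4, 6))
  rig$stage$position["z"] <- 5
  set.seed(10)
  det1 <- detect_circular_feature(render_frame(ph, rig, "fluorescence"))
  rig2 <- center_on_laser_spot(rig, det1, spot)
  set.seed(11)
  det2 <- detect_circular_feature(render_frame(ph, rig2, "fluorescence"))
  expect_lt(max(abs(det2$center_px - spot)), 1)
})
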