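# render a 63x frame focused at the soma plane with the soma on the spot,
# as the pipeline leaves things after Steps 2-3 fine focus
verify_frame <- function(ph, optics = fast_optics(), noise = TRUE) {
  soma <- ph$somas[[which.max(vapply(ph$somas, function(s)
    s$peak_intensity / (1 + s$center[["z"]]), numeric(1)))]]
  rig <- rig_state(optics, "63x")
  rig <- move_stage(rig, c(-soma$center[["x"]], -soma$center[["y"]],
                           soma$center[["z"]]))
  render_frame(ph, rig, "fluorescence", noise = noise)
}

center_det <- function(optics = fast_optics()) {
  structure(list(center_px = c(row = (optics$sensor_height_px + 1) / 2,
                               col = (optics$sensor_width_px + 1) / 2),
                 equivalent_diameter = 4), class = "soma_detection")
}

test_that("flanking ROIs are 150 x 200, symmetric, and clip-guarded", {
  rois <- flanking_rois(c(row = 240.5, col = 320.5), c(480, 640),
                        soma_radius_px = 25)
  expect_equal(rois$left[3:4], c(150, 200))
  expect_equal(rois$right[3:4], c(150, 200))
  expect_equal(rois$left[1], rois$right[1])
  # symmetric about the soma column
  expect_equal((rois$left[2] + rois$left[4]) - 320.5 + 0.5,
               -(rois$right[2] - 320.5 + 0.5), tolerance = 1.1)
  expect_error(flanking_rois(c(row = 240, col = 40), c(480, 640), 25),
               class = "axobot_reject")
})

test_that("straight-edge detector: axon present, blank and blob absent", {
  set.seed(20)
  blank <- matrix(40 + rnorm(150 * 200, 0, 12), 150, 200)
  ev0 <- detect_straight_edge(blank)
  expect_false(ev0$present)

  axon <- blank
  rows <- round(75 + 0.03 * (1:200))   # ~1.7 degrees
  axon[cbind(rows, 1:200)] <- axon[cbind(rows, 1:200)] + 120
  axon[cbind(rows + 1, 1:200)] <- axon[cbind(rows + 1, 1:200)] + 60
  ev1 <- detect_straight_edge(axon)
  expect_true(ev1$present)
  expect_lte(abs(ev1$angle), 5)

  blob <- blank
  for (r in 1:150) for (cc in 90:110) {
    if ((r - 75)^2 + (cc - 100)^2 <= 100) blob[r, cc] <- blob[r, cc] + 400
  }
  ev2 <- detect_straight_edge(blob)
  expect_false(ev2$present)
})

test_that("classification follows the stated evidence rules", {
  p <- function(strength, mi) structure(list(present = TRUE, strength = strength,
                                             angle = 0, mean_intensity_on_line = mi),
                                        class = "edge_evidence")
  a <- structure(list(present = FALSE, strength = 0, angle = 0,
                      mean_intensity_on_line = 0), class = "edge_evidence")
  expect_identical(classify_neuron(p(10, 100), a)$head_direction, "left")
  expect_identical(classify_neuron(a, p(10, 100))$head_direction, "right")
  nid <- classify_neuron(a, a)
  expect_identical(nid$classification, "not_target")
  expect_identical(nid$head_direction, "unknown")
  # both present: any brightness margin decides
  expect_identical(classify_neuron(p(10, 100), p(9, 100.1))$head_direction, "right")
  expect_identical(classify_neuron(p(9, 100.1), p(10, 100))$head_direction, "left")
})

test_that("mirror symmetry: flipping the frame flips only the head direction", {
  ph <- make_phantom(clean_params(p_posterior_process = 0), seed = 51)
  set.seed(52)
  f <- verify_frame(ph)
  det <- center_det()
  n1 <- verify_neuron(f, det)
  f2 <- f
  f2$raster <- f$raster[, ncol(f$raster):1]
  n2 <- verify_neuron(f2, det)
  expect_identical(n1$classification, "ALM")
  expect_identical(n2$classification, "ALM")
  expect_false(n1$head_direction == n2$head_direction)
})

test_that("ALM vs AVM discrimination meets the accuracy targets", {
  n <- 200
  det <- center_det()
  ok_class <- 0L; ok_head <- 0L
  pp <- clean_params()
  set.seed(500)
  for (i in seq_len(n)) {
    ph <- make_phantom(pp)
    nid <- tryCatch(verify_neuron(verify_frame(ph), det),
                    axobot_reject = function(e) NULL)
    if (!is.null(nid) && nid$classification == "ALM") {
      ok_class <- ok_class + 1L
      truth <- if (ph$orientation[1] < 0) "left" else "right"
      if (nid$head_direction == truth) ok_head <- ok_head + 1L
    }
  }
  expect_gte(ok_class / n, 0.95)
  expect_gte(ok_head / n, 0.95 * 0.95)  # orientation right in >=95% of ALM calls

  # AVM-only phantoms: false-ALM rate <= 5%
  pp_avm <- phantom_params(p_reject = c(trap = 0, soma = 0, axon = 1, ablation = 0))
  set.seed(600)
  false_alm <- 0L
  m <- 0L
  while (m < n) {
    ph <- make_phantom(pp_avm)
    # the axon class is a mix of AVM-only and weak-axon; keep AVM-only
    if (length(ph$axons) > 0) next
    m <- m + 1L
    nid <- tryCatch(verify_neuron(verify_frame(ph), det),
                    axobot_reject = function(e) NULL)
    if (!is.null(nid) && nid$classification == "ALM") false_alm <- false_alm + 1L
  }
  expect_lte(false_alm / n, 0.05)
})
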