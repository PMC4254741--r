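test_that("anterior offset move shifts the viewed field towards the head", {
  opt <- fast_optics()
  rig <- rig_state(opt, "63x")
  alm <- structure(list(classification = "ALM", head_direction = "left"),
                   class = "neuron_id")
  moved <- anterior_offset_move(rig, alm, 50)
  # world x imaged at the frame centre: w = -(stage + piezo)
  viewed_before <- -(rig$stage$position[["x"]] + rig$piezo$position[["x"]])
  viewed_after <- -(moved$stage$position[["x"]] + moved$piezo$position[["x"]])
  expect_equal(viewed_after - viewed_before, -50)  # head left = -x
  almr <- structure(list(classification = "ALM", head_direction = "right"),
                    class = "neuron_id")
  moved_r <- anterior_offset_move(rig, almr, 50)
  expect_equal(-(moved_r$stage$position[["x"]]) - viewed_before, 50)
  # identity and contract violations
  expect_identical(anterior_offset_move(rig, alm, 0)$stage, rig$stage)
  unk <- structure(list(classification = "ALM", head_direction = "unknown"),
                   class = "neuron_id")
  expect_error(anterior_offset_move(rig, unk, 50), "known head direction")
})

test_that("profile centroid is exact on symmetric and Gaussian profiles", {
  img <- matrix(0, 200, 60)
  img[96:104, ] <- 50            # symmetric block about row 100
  expect_equal(axon_profile_center(img, spot_col = 30, spot_row = 100,
                                   window = 80), 100)
  rows <- 1:200
  gauss <- matrix(rep(400 * exp(-(rows - 100.37)^2 / (2 * 2^2)), 60), 200, 60)
  expect_equal(axon_profile_center(gauss, 30, spot_row = 100, window = 120),
               100.37, tolerance = 0.05)
})

test_that("profile centroid keeps sub-pixel accuracy at SNR 10 (Monte Carlo)", {
  rows <- 1:200
  clean <- 100 * exp(-(rows - 97.3)^2 / (2 * 2^2))
  errs <- numeric(100)
  set.seed(21)
  for (i in 1:100) {
    noisy <- matrix(rep(clean, 11), 200, 11) + rnorm(200 * 11, 0, 10)
    noisy <- pmax(noisy, 0)
    errs[i] <- axon_profile_center(noisy, 6, spot_row = 100, window = 120,
                                   halfcols = 5) - 97.3
  }
  expect_lte(mean(abs(errs)), 0.5)
})

test_that("a background-level profile raises the no-axon condition", {
  set.seed(22)
  img <- matrix(40 + rnorm(200 * 60, 0, 8), 200, 60)
  expect_error(axon_profile_center(img, 30, spot_row = 100),
               class = "axobot_no_axon")
})

test_that("proportional loop: zero initial error converges with no iterations", {
  ph <- axon_only_phantom(y_um = 0)
  rig <- rig_state(fast_optics(), "63x")
  lock <- align_axon(rig, ph, control_config(), noise = FALSE)
  expect_true(lock$converged)
  expect_equal(lock$iterations, 0)
})

test_that("noiseless loop follows the contraction law and meets the 10-iteration budget", {
  px <- 6.45 / 63
  ph <- axon_only_phantom(y_um = 5)  # ~48.8 px initial error
  rig <- rig_state(fast_optics(), "63x",
                   piezo = piezo_model(backlash_deadband = 0))
  lock <- align_axon(rig, ph, control_config(gain_kp = 0.9), noise = FALSE)
  expect_true(lock$converged)
  expect_lte(lock$iterations, 10)
  expect_lte(abs(lock$final_error_px), 1)
  # |e_k| = |1 - Kp|^k * |e_0| in pixels: the piezo trajectory mirrors it
  e0 <- 5
  expected_y <- -(e0 - e0 * 0.1^(1:lock$iterations))
  expect_equal(lock$y_trajectory, expected_y, tolerance = 0.02)
})

test_that("with backlash and noise the lock still lands within ~1 px in <=10 iterations", {
  ph <- axon_only_phantom(y_um = 5)
  rig <- rig_state(fast_optics(), "63x")  # default 0.1 um deadband
  set.seed(23)
  lock <- align_axon(rig, ph, control_config(), noise = TRUE)
  expect_true(lock$converged)
  expect_lte(lock$iterations, 10)
  expect_lte(abs(lock$final_error_px), 1)
})

test_that("convergence holds over a grid of initial errors (Kp = 0.9, ideal piezo)", {
  rig <- rig_state(fast_optics(), "63x",
                   piezo = piezo_model(backlash_deadband = 0, min_step = 1e-6))
  px <- 6.45 / 63
  for (e0_px in c(5, 15, 30, 50, 70, 90)) {
    ph <- axon_only_phantom(y_um = e0_px * px)
    lock <- align_axon(rig, ph, control_config(profile_window_px = 220L),
                       noise = FALSE)
    expect_true(lock$converged, info = paste("e0 =", e0_px, "px"))
    expect_lte(lock$iterations, 10)
  }
})

test_that("corrections beyond the +/-10 um piezo travel fail the lock", {
  ph <- axon_only_phantom(y_um = 12)
  rig <- rig_state(fast_optics(768L, 520L), "63x")
  lock <- align_axon(rig, ph, control_config(profile_window_px = 260L),
                     noise = FALSE)
  expect_false(lock$converged)
})

test_that("execute_axotomy severs the axon only from a converged lock", {
  ph <- axon_only_phantom(y_um = 1)
  rig <- rig_state(fast_optics(), "63x")
  lock <- align_axon(rig, ph, control_config(), noise = FALSE)
  expect_true(lock$converged)
  res <- execute_axotomy(lock$rig, ph, lock)
  expect_true(res$outcome$hit)
  expect_lte(res$outcome$lateral_error, 1 * 6.45 / 63)
  expect_equal(res$outcome$pulses, 300)
  expect_equal(res$outcome$pulse_energy, 4)

  bad <- lock; bad$converged <- FALSE
  expect_error(execute_axotomy(lock$rig, ph, bad), "non-converged")

  # a residual error of 4 px (~0.41 um) exceeds the 0.31 um spot radius
  rig4 <- lock$rig
  rig4$piezo$position["y"] <- rig4$piezo$position["y"] + 4 * 6.45 / 63
  forced <- lock; forced$rig <- rig4
  res4 <- execute_axotomy(rig4, ph, forced)
  expect_false(res4$outcome$hit)
  expect_gt(res4$outcome$lateral_error, 0.31)
})
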