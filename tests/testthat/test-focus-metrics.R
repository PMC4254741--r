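test_that("LoG kernel is zero-sum and rejects DC", {
  k <- log_kernel(sigma = 2)
  expect_equal(sum(k), 0, tolerance = 1e-12)
  expect_equal(dim(k), c(17, 17))
  resp <- log_filter(matrix(7.3, 30, 40), sigma = 2)
  expect_lt(max(abs(resp)), 1e-10)
  expect_error(log_filter(matrix(1, 5, 5), sigma = 0), "sigma")
  expect_error(log_kernel(sigma = -1), "sigma")
})

test_that("LoG filtering matches the brute-force convolution oracle", {
  set.seed(11)
  img <- matrix(runif(20 * 24, 0, 100), 20, 24)
  img[10, 12] <- 500  # point source
  k <- log_kernel(sigma = 2, truncate = 2)  # small kernel keeps the oracle fast
  got <- axobot:::conv2_reflect_cpp(img, k)
  want <- oracle_conv2(img, k)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
  # default sigma path too, on a smaller image
  img2 <- matrix(runif(12 * 12), 12, 12)
  expect_lt(max(abs(log_filter(img2, 2) - oracle_conv2(img2, log_kernel(2)))) /
              max(abs(oracle_conv2(img2, log_kernel(2)))), 1e-6)
})

test_that("LoG filtering is linear", {
  set.seed(12)
  x <- matrix(runif(400), 20)
  y <- matrix(runif(400), 20)
  lhs <- log_filter(3 * x - 2 * y, 2)
  rhs <- 3 * log_filter(x, 2) - 2 * log_filter(y, 2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("focus variance is the population variance with known closed forms", {
  expect_equal(focus_variance(matrix(4.2, 13, 9)), 0)
  half <- matrix(c(rep(0, 50), rep(10, 50)), 10)
  expect_equal(focus_variance(half), 25)
  set.seed(13)
  img <- matrix(rnorm(35 * 17, 50, 12), 35)
  expect_equal(focus_variance(img), oracle_variance(img), tolerance = 1e-10)
  expect_error(focus_variance(matrix(numeric(0), 0, 0)), "nonempty")
})

test_that("focus variance: offset-invariant, gain-quadratic", {
  set.seed(14)
  img <- matrix(runif(300, 0, 100), 15)
  expect_equal(focus_variance(img + 37), focus_variance(img), tolerance = 1e-9)
  expect_equal(focus_variance(3 * img), 9 * focus_variance(img), tolerance = 1e-9)
})

render_soma_stack <- function(z_soma, zs, optics = fast_optics(192L, 160L),
                              noise = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ph <- soma_phantom(z_um = z_soma)
  frames <- lapply(zs, function(z) {
    rig <- rig_state(optics, "63x")
    rig$stage$position["z"] <- z
    render_frame(ph, rig, "fluorescence", noise = noise)
  })
  zstack(frames, zs)
}

test_that("fine_focus returns the slice closest to the true focal plane", {
  zs <- seq(3.6, 7.8, by = 0.7)
  st <- render_soma_stack(z_soma = 5.7, zs = zs)
  expect_equal(fine_focus(st), which.min(abs(zs - 5.7)))
  # single-frame stack and tie rule
  one <- zstack(list(matrix(runif(100), 10)), 0)
  expect_equal(fine_focus(one), 1)
  same <- matrix(runif(100), 10)
  expect_equal(fine_focus(zstack(list(same, same, same), 0:2)), 1)
  expect_error(fine_focus(zstack(list(), numeric(0))), "empty")
})

test_that("the focus metric is unimodal about the peak for noiseless stacks", {
  zs <- seq(2, 9, by = 0.7)
  st <- render_soma_stack(z_soma = 5.5, zs = zs)
  v <- vapply(st$frames, function(f) focus_variance(log_filter(f$raster, 2)),
              numeric(1))
  k <- which.max(v)
  expect_true(all(diff(v[seq_len(k)]) > 0))
  expect_true(all(diff(v[k:length(v)]) < 0))
})

test_that("axon_focus maximizes the mean intensity in the axon neighbourhood", {
  opt <- fast_optics(192L, 160L)
  ph <- axon_only_phantom(y_um = 0, z_um = 3)
  zs <- seq(2, 4, by = 0.35)
  frames <- lapply(zs, function(z) {
    rig <- rig_state(opt, "63x"); rig$stage$position["z"] <- z
    render_frame(ph, rig, "fluorescence", noise = FALSE)
  })
  roi <- c(50, 40, 60, 100)
  expect_equal(axon_focus(zstack(frames, zs), roi), which.min(abs(zs - 3)))
  # identical slices break ties to index 1; all-zero region warns
  same <- matrix(5, 160, 192)
  expect_equal(axon_focus(zstack(list(same, same), 1:2), roi), 1)
  z0 <- matrix(0, 160, 192)
  expect_warning(idx <- axon_focus(zstack(list(z0, z0), 1:2), roi), "zero")
  expect_equal(idx, 1)
  expect_error(axon_focus(zstack(list(same), 1), c(0, 0, 500, 500)),
               "roi outside frame")
})

test_that("zstack validates its contract", {
  expect_error(zstack(list(matrix(1, 2, 2)), c(1, 2)), "mismatch")
  expect_error(zstack(list(matrix(1, 2, 2), matrix(1, 2, 2)), c(1, 1)),
               "monotone")
})
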