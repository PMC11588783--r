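test_that("Gaussian smoothing: constants, identity at sigma 0, kernel values", {
  const <- image_volume(matrix(3.7, 9, 9))
  expect_equal(smooth_volume(const, 2)$data, const$data)

  set.seed(4)
  img <- image_volume(matrix(runif(81), 9, 9))
  expect_identical(smooth_volume(img, 0)$data, img$data)
  expect_error(smooth_volume(img, -1), "sigma")

  # unit impulse reproduces the explicit separable kernel
  imp <- matrix(0, 9, 9)
  imp[5, 5] <- 1
  sm <- smooth_volume(image_volume(imp), 1)$data
  k <- exp(-(-4:4)^2 / 2)
  k <- k / sum(k)
  expect_equal(sm, k %o% k, tolerance = 1e-12)

  # mean preserved under reflect boundaries
  expect_equal(mean(smooth_volume(img, 2)$data), mean(img$data),
               tolerance = 1e-12)
})

test_that("Sobel magnitude matches the hand-computed step response", {
  const <- image_volume(array(2, c(6, 6, 6)))
  expect_true(all(gradient_magnitude(const)$data == 0))

  step <- image_volume(cbind(matrix(0, 16, 8), matrix(1, 16, 8)))
  mag <- gradient_magnitude(step)$data
  expected <- matrix(0, 16, 16)
  expected[, 8:9] <- 4            # [-1 0 1] x [1 2 1] across the step
  expect_equal(mag, expected)

  set.seed(9)
  img <- matrix(runif(15 * 12), 15, 12)
  mag1 <- gradient_magnitude(image_volume(img))$data
  mag2 <- gradient_magnitude(image_volume(img[, ncol(img):1]))$data
  expect_equal(mag1, mag2[, ncol(img):1], tolerance = 1e-12)
})

test_that("thresholding: fixed rule, degenerate input, Otsu vs brute force", {
  zeros <- image_volume(matrix(0, 8, 8))
  expect_warning(
    em <- threshold_edges(zeros, edge_params(threshold_method = "otsu")),
    "degenerate")
  expect_false(any(em$mask))

  g <- matrix(0.1, 10, 10)
  g[1:10] <- 0.9
  em <- threshold_edges(image_volume(g),
                        edge_params(threshold_method = "fixed",
                                    threshold_value = 0.5,
                                    normalize = FALSE))
  expect_identical(em$mask, g == 0.9)

  # bimodal gradient: histogram Otsu lands between the modes, near the
  # exhaustive-search optimum
  set.seed(21)
  vals <- c(abs(rnorm(300, 0.1, 0.03)), abs(rnorm(80, 0.8, 0.05)))
  thr <- otsu_threshold(vals)
  ref <- bf_otsu(vals)
  expect_gt(thr, 0.25)
  expect_lt(thr, 0.65)
  expect_equal(thr, ref, tolerance = 0.05)
  gm <- image_volume(matrix(vals[1:361], 19, 19))
  em <- threshold_edges(gm, edge_params(normalize = FALSE))
  expect_identical(em$mask, gm$data >= em$threshold)
})

test_that("composite edge map equals the explicit three-step chain", {
  set.seed(5)
  img <- image_volume(matrix(runif(256), 16, 16))
  p <- edge_params(smooth_sigma = 1.5)
  em <- compute_edge_map(img, p)
  chained <- threshold_edges(gradient_magnitude(smooth_volume(img, 1.5)), p)
  expect_identical(em$mask, chained$mask)
  expect_identical(em$threshold, chained$threshold)

  expect_warning(emc <- compute_edge_map(image_volume(matrix(1, 8, 8))),
                 "degenerate")
  expect_false(any(emc$mask))
})

test_that("edge mask is invariant to affine intensity rescaling", {
  set.seed(6)
  base <- smooth_volume(image_volume(matrix(rnorm(400), 20, 20)), 1)$data
  for (method in c("otsu", "percentile")) {
    p <- edge_params(threshold_method = method,
                     threshold_value = if (method == "percentile") 75,
                     normalize = TRUE)
    m1 <- compute_edge_map(image_volume(base), p)$mask
    m2 <- compute_edge_map(image_volume(3.2 * base + 10), p)$mask
    expect_identical(m1, m2)
  }
})

test_that("raising a fixed threshold never adds edge voxels", {
  set.seed(7)
  img <- image_volume(matrix(runif(400), 20, 20))
  prev <- NULL
  for (t in c(0.1, 0.3, 0.5, 0.8)) {
    m <- compute_edge_map(img, edge_params(threshold_method = "fixed",
                                           threshold_value = t))$mask
    if (!is.null(prev)) expect_true(all(prev | !m))
    prev <- m
  }
})

test_that("phantom interfaces: bright ridge detected, dropout ridge not", {
  # one bright and one signal-free interface on an otherwise flat image
  img <- matrix(0.3, 40, 40)
  bright <- matrix(FALSE, 40, 40); bright[12, 6:34] <- TRUE
  dropout <- matrix(FALSE, 40, 40); dropout[30, 6:34] <- TRUE
  d <- distance_transform(bright)
  img <- img + 0.9 * exp(-d^2 / 2)
  em <- compute_edge_map(image_volume(img))
  near_edge <- dilate_mask(em$mask, 1)
  expect_gte(mean(near_edge[bright]), 0.9)
  expect_lte(mean(near_edge[dropout]), 0.1)
})

test_that("3D gradient operates natively and slice-wise on request", {
  set.seed(8)
  vol <- image_volume(array(runif(10 * 12 * 14), c(10, 12, 14)))
  g3 <- gradient_magnitude(vol)$data
  gs <- gradient_magnitude(vol, mode_2d_slicewise = TRUE)$data
  expect_equal(dim(g3), dim(vol$data))
  # slice-wise mode ignores the z axis: a volume varying only along z has
  # zero slice-wise gradient but nonzero native 3D gradient
  ramp <- image_volume(array(rep(seq_len(10), 12 * 14), c(10, 12, 14)))
  expect_true(all(gradient_magnitude(ramp,
                                     mode_2d_slicewise = TRUE)$data == 0))
  expect_gt(max(gradient_magnitude(ramp)$data), 0)
  expect_false(identical(g3, gs))
})
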