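test_that("scalar_target sums the selected class scores", {
  scores <- array(0, c(3, 4, 4))
  scores[2, 1, 1] <- 1.5
  scores[2, 2, 3] <- 2.5
  scores[1, , ] <- 99            # other classes must not leak in
  one <- matrix(FALSE, 4, 4); one[1, 1] <- TRUE
  expect_equal(scalar_target(scores, cam_target(1L, one)), 1.5)
  two <- matrix(FALSE, 4, 4); two[1, 1] <- TRUE; two[2, 3] <- TRUE
  expect_equal(scalar_target(scores, cam_target(1L, two)), 4)
  expect_equal(scalar_target(scores, cam_target(1L, matrix(TRUE, 4, 4))),
               sum(scores[2, , ]))
  expect_error(cam_target(1L, matrix(FALSE, 4, 4)), "empty")
})

test_that("fixed_linear CAM matches the closed form for a linear head", {
  set.seed(31)
  img <- image_volume(matrix(runif(16), 4, 4))
  m <- toy_model_fixture("fixed_linear")
  ps <- matrix(FALSE, 4, 4); ps[2:3, 2] <- TRUE
  cam <- compute_cam(m, img, cam_target(2L, ps), "features")
  # with scores = V %*% A + c, the pooled gradient is V[c+1, f] * |S| / (wh)
  V <- m$params$V
  expected_w <- V[3, ] * sum(ps) / 16
  expect_equal(cam$weights, expected_w, tolerance = 1e-12)
  A <- model_forward(m, img)$acts$features
  pre <- array(0, c(4, 4))
  for (f in 1:4) pre <- pre + expected_w[f] * A[f, , ]
  expect_equal(cam$map, pmax(pre, 0), tolerance = 1e-12)
})

test_that("a class disconnected from the layer yields an all-zero CAM", {
  m <- toy_model_fixture("fixed_linear")
  m$params$V[3, ] <- 0           # class id 2 no longer reads the features
  img <- image_volume(matrix(seq(0, 1, length.out = 16), 4, 4))
  cam <- compute_cam(m, img, cam_target(2L, matrix(TRUE, 4, 4)), "features")
  expect_true(all(cam$map == 0))
  expect_true(all(cam$weights == 0))
})

test_that("analytic CAM equals the finite-difference oracle", {
  set.seed(32)
  img <- image_volume(matrix(runif(64), 8, 8))
  m <- toy_model_fixture("fixed_linear")
  ps <- matrix(FALSE, 8, 8); ps[3:6, 4] <- TRUE
  tg <- cam_target(1L, ps)
  cam <- compute_cam(m, img, tg, "features")
  fd <- fd_cam(m, img, tg, "features")
  expect_lt(max(abs(cam$map - fd)) / max(max(abs(fd)), 1e-12), 1e-3)
})

test_that("CAM properties: non-negativity, reconstruction, determinism", {
  set.seed(33)
  img <- image_volume(matrix(runif(64), 8, 8))
  m <- trained_unet()
  ps <- matrix(FALSE, 8, 8); ps[2:7, 3:5] <- TRUE
  tg <- cam_target(1L, ps)
  cam1 <- compute_cam(m, img, tg)
  cam2 <- compute_cam(m, img, tg)
  expect_identical(cam1$map, cam2$map)
  expect_true(all(cam1$map >= 0))
  # exact reconstruction from stored weights and activations
  pre <- array(0, dim(cam1$map))
  for (f in seq_along(cam1$weights)) {
    pre <- pre + cam1$weights[f] * cam1$activations[f, , ]
  }
  expect_identical(cam1$map, pmax(pre, 0))
  expect_error(compute_cam(m, img, tg, layer = "nope"), "available layers")
})

test_that("pre-ReLU maps are additive over disjoint pixel sets", {
  set.seed(34)
  img <- image_volume(matrix(runif(64), 8, 8))
  m <- trained_unet()
  s1 <- matrix(FALSE, 8, 8); s1[2:4, 2:4] <- TRUE
  s2 <- matrix(FALSE, 8, 8); s2[6:7, 5:7] <- TRUE
  cam_a <- compute_cam(m, img, cam_target(1L, s1))
  cam_b <- compute_cam(m, img, cam_target(1L, s2))
  cam_u <- compute_cam(m, img, cam_target(1L, s1 | s2))
  expect_equal(cam_u$pre_map, cam_a$pre_map + cam_b$pre_map,
               tolerance = 1e-12)
  expect_equal(cam_u$weights, cam_a$weights + cam_b$weights,
               tolerance = 1e-12)
})

test_that("cam_for_split returns a pair and flags empty parts", {
  ph <- generate_phantom(phantom_spec(shape = c(64L, 64L), seed = 77L))
  m <- trained_unet()
  em <- compute_edge_map(ph$image)
  split <- split_all_classes(ph$labels, em, tolerance_radius = 1)[[1]]
  pair <- cam_for_split(m, ph$image, split)
  expect_s3_class(pair$distinct, "us_cam")
  expect_s3_class(pair$completed, "us_cam")
  expect_identical(dim(pair$distinct$upsampled), dim(ph$image$data))

  empty_split <- split_border(split$border, array(TRUE, dim(split$border)),
                              class_id = split$class_id)
  expect_warning(p2 <- cam_for_split(m, ph$image, empty_split),
                 "completed border empty")
  expect_null(p2$completed)
  expect_s3_class(p2$distinct, "us_cam")
})

test_that("distinct-border CAM concentrates on visible interfaces", {
  ph <- generate_phantom(phantom_spec(shape = c(64L, 64L), seed = 78L))
  m <- trained_unet()
  em <- compute_edge_map(ph$image)
  splits <- split_all_classes(ph$labels, em, tolerance_radius = 1)
  cam <- cam_for_split(m, ph$image, splits[[2]])$distinct
  band <- dilate_mask(ph$designed_distinct, 2)
  interior <- !dilate_mask(ph$designed_distinct | ph$designed_completed, 6)
  expect_gt(mean(cam$upsampled[band]), mean(cam$upsampled[interior]))
})

test_that("perturbation identities and patch response", {
  ph <- generate_phantom(phantom_spec(shape = c(64L, 64L), seed = 79L))
  m <- trained_unet()
  border <- extract_border(ph$labels, 2L)
  tg <- cam_target(2L, border)
  id1 <- perturb_and_compare(m, ph$image, tg,
                             perturbation = "gaussian_noise",
                             params = list(sd = 0))
  expect_equal(id1$similarity, 1)
  expect_equal(id1$mean_region_baseline, id1$mean_region_perturbed)
  id2 <- perturb_and_compare(m, ph$image, tg,
                             perturbation = "contrast_scale",
                             params = list(factor = 1))
  expect_equal(id2$similarity, 1)

  # zero a patch over a visible interface: local distinct-target CAM drops
  dd <- which(ph$designed_distinct, arr.ind = TRUE)
  cy <- dd[which.min(dd[, 1]), ]
  patch <- c(max(1, cy[1] - 5), min(64, cy[1] + 5),
             max(1, cy[2] - 5), min(64, cy[2] + 5))
  em <- compute_edge_map(ph$image)
  sp <- split_all_classes(ph$labels, em, tolerance_radius = 1)[[1]]
  res <- perturb_and_compare(m, ph$image,
                             cam_target(1L, sp$distinct),
                             perturbation = "zero_patch",
                             params = list(patch = patch))
  expect_lt(res$mean_region_perturbed, res$mean_region_baseline)
  expect_error(perturb_and_compare(m, ph$image, tg,
                                   perturbation = "zero_patch",
                                   params = list(patch = c(0, 5, 1, 5))),
               "patch")
})
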