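test_that("phantoms are deterministic and honor the designed fraction", {
  sp <- phantom_spec(seed = 7, dropout_fraction = 0.4)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$designed_completed, b$designed_completed)

  border <- a$designed_distinct | a$designed_completed
  frac <- sum(a$designed_completed) / sum(border)
  expect_lt(abs(frac - 0.4), 0.02)

  # designed masks partition the union of all structure borders
  all_border <- array(FALSE, dim(a$labels$data))
  for (cid in label_classes(a$labels)) {
    all_border <- all_border | extract_border(a$labels, cid)
  }
  expect_identical(border, all_border)
  expect_false(any(a$designed_distinct & a$designed_completed))
})

test_that("dropout extremes produce one-sided designed splits", {
  none <- generate_phantom(phantom_spec(seed = 3, dropout_fraction = 0))
  expect_false(any(none$designed_completed))
  expect_gt(sum(none$designed_distinct), 0)
  expect_warning(
    full <- generate_phantom(phantom_spec(seed = 3, dropout_fraction = 1)),
    "no distinct")
  expect_false(any(full$designed_distinct))
  expect_gt(sum(full$designed_completed), 0)
})

test_that("noise-free phantoms recover the designed split from edges", {
  jac <- vapply(1:5, function(s) {
    ph <- generate_phantom(phantom_spec(seed = s, speckle_sd = 0))
    em <- compute_edge_map(ph$image)
    border <- ph$designed_distinct | ph$designed_completed
    rec <- split_border(border, em, tolerance_radius = 1)
    sum(rec$distinct & ph$designed_distinct) /
      sum(rec$distinct | ph$designed_distinct)
  }, numeric(1))
  expect_gte(min(jac), 0.9)
})

test_that("recovery degrades gracefully as speckle grows", {
  jac_at <- function(sd_speckle) {
    mean(vapply(1:5, function(s) {
      ph <- generate_phantom(phantom_spec(seed = s,
                                          speckle_sd = sd_speckle))
      em <- compute_edge_map(ph$image)
      border <- ph$designed_distinct | ph$designed_completed
      rec <- split_border(border, em, tolerance_radius = 1)
      sum(rec$distinct & ph$designed_distinct) /
        sum(rec$distinct | ph$designed_distinct)
    }, numeric(1)))
  }
  j0 <- jac_at(0); j2 <- jac_at(0.3); j3 <- jac_at(0.6)
  expect_gte(j0, j2)
  expect_gt(j2, j3)
  expect_gt(j0, 0.9)
})

test_that("3D phantoms satisfy the same designed-split contract", {
  sp <- phantom_spec(shape = c(24L, 48L, 48L), seed = 11L,
                     dropout_fraction = 0.3)
  ph <- generate_phantom(sp)
  expect_equal(dim(ph$image$data), c(24L, 48L, 48L))
  border <- ph$designed_distinct | ph$designed_completed
  expect_gt(sum(border), 0)
  frac <- sum(ph$designed_completed) / sum(border)
  expect_lt(abs(frac - 0.3), 0.02)
  all_border <- array(FALSE, dim(ph$labels$data))
  for (cid in label_classes(ph$labels)) {
    all_border <- all_border | extract_border(ph$labels, cid)
  }
  expect_identical(border, all_border)
})

test_that("simulated predictions: identity at 0, tolerant dilation, decay", {
  ph <- generate_phantom(phantom_spec(shape = c(64L, 64L), seed = 21L))
  same <- simulate_prediction(ph$labels, "dilate", 0)
  expect_identical(same$data, ph$labels$data)

  # dilation by r stays a perfect match under match_tolerance >= r
  disc <- matrix(0L, 32, 32)
  dd <- (row(disc) - 16)^2 + (col(disc) - 16)^2 <= 64
  disc[dd] <- 1L
  disc_lab <- label_volume(disc)
  pred <- simulate_prediction(disc_lab, "dilate", 2)
  gs <- split_border(extract_border(disc_lab, 1),
                     array(TRUE, dim(disc)), class_id = 1L)
  row2 <- tp_decomposition(gs, extract_border(pred, 1),
                           match_tolerance = 2)
  expect_equal(row2$tp_total_pct, 100)

  # stronger elastic jitter lowers the mean true-positive fraction
  tp_at <- function(mag) {
    mean(vapply(1:10, function(s) {
      p <- simulate_prediction(ph$labels, "elastic_jitter", mag, seed = s)
      sp <- split_border(extract_border(ph$labels, 1L),
                         array(TRUE, dim(ph$labels$data)),
                         class_id = 1L)
      tp_decomposition(sp, extract_border(p, 1L),
                       match_tolerance = 1)$tp_total_pct
    }, numeric(1)))
  }
  expect_gt(tp_at(1), tp_at(4))
  expect_error(simulate_prediction(ph$labels, "dilate", -1), "magnitude")
})
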