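test_that("dice handles the analytic cases", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[2:3, 2:3] <- TRUE   # overlap 1 voxel
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, matrix(FALSE, 4, 4)), 0)
  disj <- matrix(FALSE, 4, 4); disj[4, 4] <- TRUE
  expect_equal(dice(a, disj), 0)
  p <- matrix(FALSE, 4, 4); p[1, 1:4] <- TRUE
  g <- matrix(FALSE, 4, 4); g[1, 3:4] <- TRUE; g[2, 3:4] <- TRUE
  expect_equal(dice(p, g), 0.5)                   # |P|=4,|G|=4,overlap 2
  expect_equal(dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)
})

test_that("hd95 and nsd match analytic values and brute force", {
  m <- matrix(FALSE, 9, 9); m[4:6, 4:6] <- TRUE
  expect_equal(hd95(m, m), 0)
  expect_equal(nsd(m, m, tau = 0.5), 1)

  a <- matrix(FALSE, 9, 9); a[5, 2] <- TRUE
  b <- matrix(FALSE, 9, 9); b[5, 5] <- TRUE       # 3 voxels apart, 1 mm
  expect_equal(hd95(a, b), 3)
  expect_equal(nsd(a, b, tau = 1), 0)             # farther than tau

  # constructed distances {0,1,2,5} pooled with the reverse direction {0}
  gt <- matrix(FALSE, 3, 10); gt[2, 2] <- TRUE
  pr <- matrix(FALSE, 3, 10); pr[2, c(2, 3, 4, 7)] <- TRUE
  expect_equal(nsd(pr, gt, tau = 2), 0.8)         # 4 of 5 pooled within 2
  expect_equal(nsd(pr, gt, tau = 2), bf_nsd(pr, gt, c(1, 1), 2))
  expect_equal(hd95(pr, gt), bf_hd95(pr, gt))

  expect_error(hd95(matrix(FALSE, 3, 3), m[1:3, 1:3]), "empty")
})

test_that("surface metrics equal brute force on random masks", {
  for (seed in 1:6) {
    p2 <- random_mask(c(16L, 16L), p = 0.6, seed = seed)
    g2 <- random_mask(c(16L, 16L), p = 0.6, seed = seed + 50L)
    if (!any(p2) || !any(g2)) next
    sp <- c(0.7, 1.3)
    expect_equal(hd95(p2, g2, sp), bf_hd95(p2, g2, sp), tolerance = 1e-10)
    expect_equal(nsd(p2, g2, sp, tau = 1), bf_nsd(p2, g2, sp, 1),
                 tolerance = 1e-12)
    expect_equal(dice(p2, g2), bf_dice(p2, g2))
  }
  for (seed in 1:3) {
    p3 <- random_mask(c(10L, 10L, 10L), p = 0.6, seed = seed)
    g3 <- random_mask(c(10L, 10L, 10L), p = 0.6, seed = seed + 50L)
    sp <- c(0.5, 1, 0.8)
    expect_equal(hd95(p3, g3, sp), bf_hd95(p3, g3, sp), tolerance = 1e-10)
    expect_equal(nsd(p3, g3, sp, tau = 0.9), bf_nsd(p3, g3, sp, 0.9),
                 tolerance = 1e-12)
  }
})

test_that("tp decomposition counts match enumeration and stay additive", {
  # 20-voxel reference line, 12 distinct / 8 completed
  border <- matrix(FALSE, 12, 30); border[6, 3:22] <- TRUE
  edges <- matrix(FALSE, 12, 30); edges[6, 3:14] <- TRUE
  gs <- split_border(border, edges, class_id = 1L)
  pred <- matrix(FALSE, 12, 30)
  pred[6, c(3:12, 15:20)] <- TRUE        # 10 distinct + 6 completed matched
  row <- tp_decomposition(gs, pred, match_tolerance = 0)
  expect_equal(row$tp_total_pct, 80)
  expect_equal(row$tp_distinct_pct, 50)
  expect_equal(row$tp_completed_pct, 30)
  expect_equal(row$reference_distinct_pct, 60)

  perfect <- tp_decomposition(gs, border, match_tolerance = 0)
  expect_equal(perfect$tp_total_pct, 100)
  expect_equal(perfect$tp_distinct_pct, 60)

  expect_warning(zero <- tp_decomposition(gs, matrix(FALSE, 12, 30)),
                 "empty prediction")
  expect_equal(zero$tp_total_pct, 0)
  expect_equal(zero$tp_completed_pct, 0)
})

test_that("prediction equal to ground truth scores 100 for any split", {
  for (seed in 1:8) {
    lab <- random_labels(c(24L, 24L), seed = seed)
    edge <- random_mask(c(24L, 24L), p = 0.5, seed = seed + 9L)
    for (s in split_all_classes(lab, edge)) {
      row <- tp_decomposition(s, s$border, match_tolerance = 0)
      expect_equal(row$tp_total_pct, 100)
      expect_equal(row$tp_distinct_pct + row$tp_completed_pct, 100)
      expect_equal(row$reference_distinct_pct + row$reference_completed_pct,
                   100)
    }
  }
})

test_that("case_metrics returns per-class rows with NA for empty classes", {
  lab <- random_labels(c(20L, 20L), seed = 13L)
  pred_data <- lab$data
  pred_data[pred_data == 3L] <- 0L       # class 3 missing from prediction
  pred <- label_volume(pred_data)
  m <- case_metrics(pred, lab, case_id = "c1")
  expect_setequal(m$class_id, label_classes(lab))
  expect_equal(m$dice[m$class_id == 3], 0)
  expect_true(is.na(m$hd95_mm[m$class_id == 3]))
  expect_true(all(m$dice >= 0 & m$dice <= 1))
})

test_that("aggregation gives mean and sample sd with single-row sd 0", {
  rows <- tibble::tibble(case_id = c("a", "b"), v = c(80, 84))
  agg <- aggregate_metrics(rows)
  expect_equal(agg$mean[agg$metric == "v"], 82)
  expect_equal(agg$sd[agg$metric == "v"], sd(c(80, 84)))
  one <- aggregate_metrics(rows[1, ])
  expect_equal(one$sd, 0)
  expect_equal(one$mean, 80)

  # linearity: mean tp_distinct + mean tp_completed = mean tp_total
  set.seed(2)
  tp_d <- runif(6, 20, 50); tp_c <- runif(6, 10, 40)
  tbl <- tibble::tibble(tp_distinct_pct = tp_d, tp_completed_pct = tp_c,
                        tp_total_pct = tp_d + tp_c)
  agg2 <- aggregate_metrics(tbl)
  expect_equal(agg2$mean[agg2$metric == "tp_distinct_pct"] +
                 agg2$mean[agg2$metric == "tp_completed_pct"],
               agg2$mean[agg2$metric == "tp_total_pct"])
})

test_that("class weights are inverse-frequency, normalized, and guarded", {
  lab <- label_volume(matrix(c(rep(0L, 8), rep(1L, 4), rep(2L, 4)), 4, 4))
  w <- compute_class_weights(lab, 3L)
  expect_equal(w$frequency, c(0.5, 0.25, 0.25))
  expect_equal(w$weight, c(0.2, 0.4, 0.4))
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)

  for (seed in 1:5) {
    labs <- lapply(1:3, function(i) random_labels(c(16L, 16L),
                                                  seed = seed * 10 + i))
    ww <- compute_class_weights(labs, 4L)
    expect_equal(sum(ww$weight), 1, tolerance = 1e-12)
    expect_true(all(ww$weight > 0))
  }
  expect_error(compute_class_weights(lab, 4L), "absent.*3")
})
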