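# Six-metric suite: brute-force oracle equivalence, identities, degenerate
# conventions, and dataset-level aggregation.

test_that("dice and IoU match counting oracles and their functional identity", {
  set.seed(20)
  # fixed worked example: 2x2 prediction block inside a 2-row ground truth
  pred <- matrix(0, 4, 4); pred[1:2, 1:2] <- 1
  gt <- matrix(0, 4, 4); gt[1:2, ] <- 1
  expect_equal(dice(pred, gt), 2 * 4 / (4 + 8), tolerance = 1e-12)
  expect_equal(iou_metric(pred, gt), 4 / 8, tolerance = 1e-12)
  for (k in 1:100) {
    pr <- random_pair(16L)
    d <- dice(pr$pred, pr$gt); j <- iou_metric(pr$pred, pr$gt)
    expect_lt(abs(d - oracle_dice(pr$pred, pr$gt)), 1e-6)
    expect_lt(abs(j - oracle_iou(pr$pred, pr$gt)), 1e-6)
    expect_lt(abs(d - 2 * j / (1 + j)), 1e-10)
  }
  g <- blob_mask(8L)
  expect_equal(dice(g, g), 1)
  expect_equal(iou_metric(g, g), 1)
  disj <- matrix(0, 8, 8); disj[7:8, 7:8] <- 1
  expect_equal(dice(disj, blob_mask(8L)), 0)
  expect_equal(dice(matrix(0, 4, 4), matrix(0, 4, 4)), 1)  # empty-vs-empty
})

test_that("MAE matches the loop oracle and its extremes", {
  set.seed(21)
  for (k in 1:50) {
    pr <- random_pair(16L)
    expect_lt(abs(mae(pr$pred, pr$gt) - oracle_mae(pr$pred, pr$gt)), 1e-6)
  }
  g <- blob_mask(8L)
  expect_equal(mae(g, g), 0)
  expect_equal(mae(1 - g, g), 1)
})

test_that("weighted F-measure: perfection, inversion, boundedness", {
  g <- blob_mask(16L)
  expect_equal(weighted_fmeasure(g, g), 1, tolerance = 1e-6)
  expect_lt(weighted_fmeasure(1 - g, g), 1e-6)
  set.seed(22)
  for (k in 1:200) {
    pr <- random_pair(16L)
    if (sum(pr$gt) == 0) next
    v <- weighted_fmeasure(pr$pred, pr$gt)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_warning(v <- weighted_fmeasure(matrix(0.2, 4, 4), matrix(0, 4, 4)),
                 "empty ground truth")
  expect_true(is.na(v))
})

test_that("weighted F-measure discounts remote errors more than near ones", {
  g <- matrix(0, 32, 32); g[14:18, 14:18] <- 1
  near <- g; near[13, 14:18] <- 1     # false positives hugging the boundary
  far <- g; far[1, 1:5] <- 1          # same count of remote false positives
  expect_gt(weighted_fmeasure(far, g), 0)
  expect_gt(weighted_fmeasure(near, g), weighted_fmeasure(far, g) - 0.2)
  # remote errors are weighted up (B > 1 away from the object), so the far
  # map scores lower
  expect_lt(weighted_fmeasure(far, g), weighted_fmeasure(near, g))
})

test_that("S-measure: perfection, degenerate conventions, monotone blending", {
  g <- blob_mask(16L)
  expect_equal(s_measure(g, g), 1, tolerance = 1e-6)
  expect_equal(s_measure(matrix(0.3, 8, 8), matrix(0, 8, 8)), 0.7,
               tolerance = 1e-12)
  expect_equal(s_measure(matrix(0.3, 8, 8), matrix(1, 8, 8)), 0.3,
               tolerance = 1e-12)
  set.seed(23)
  for (k in 1:20) {
    pr <- random_pair(16L)
    if (sum(pr$gt) %in% c(0, 256)) next
    s0 <- s_measure(pr$pred, pr$gt)
    s1 <- s_measure(0.5 * pr$pred + 0.5 * pr$gt, pr$gt)
    s2 <- s_measure(pr$gt, pr$gt)
    expect_gte(s1, s0 - 1e-9)
    expect_gte(s2, s1 - 1e-9)
    expect_gte(s0, 0); expect_lte(s0, 1)
  }
})

test_that("max E-measure agrees with an independent implementation", {
  g <- blob_mask(16L)
  expect_equal(e_measure_max(g, g), 1, tolerance = 1e-6)
  # constant 0.5 prediction against half-foreground truth
  gt2 <- matrix(0, 8, 8); gt2[, 1:4] <- 1
  p2 <- matrix(0.5, 8, 8)
  expect_lt(abs(e_measure_max(p2, gt2) - oracle_e_measure_max(p2, gt2)), 1e-6)
  set.seed(24)
  for (k in 1:10) {
    pr <- random_pair(12L)
    expect_lt(abs(e_measure_max(pr$pred, pr$gt) -
                    oracle_e_measure_max(pr$pred, pr$gt)), 1e-6)
    # the max over thresholds dominates the score at 0.5
    e05 <- oracle_e_measure(as.numeric(pr$pred >= 0.5), as.numeric(pr$gt))
    expect_gte(e_measure_max(pr$pred, pr$gt), e05 - 1e-9)
  }
})

test_that("perfect predictions maximize the five agreement metrics and zero MAE", {
  set.seed(25)
  for (k in 1:50) {
    g <- (matrix(runif(64), 8) > runif(1, 0.2, 0.8)) * 1
    if (sum(g) == 0 || sum(g) == 64) next
    m <- evaluate_pair(g, g)
    expect_equal(unname(m[c("mDice", "mIOU", "wFb", "Smeasure", "Emax")]),
                 rep(1, 5), tolerance = 1e-6)
    expect_equal(unname(m[["MAE"]]), 0)
  }
})

test_that("dataset evaluation aggregates per-image means in benchmark column order", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "pred")); dir.create(file.path(td, "gt"))
  set.seed(26)
  masks <- list(blob_mask(32L), blob_mask(32L, cx = 10, cy = 20, r = 6))
  for (i in 1:2) {
    f <- sprintf("img_%d.png", i)
    write_mask_png(masks[[i]], file.path(td, "gt", f))
    write_mask_png(masks[[i]], file.path(td, "pred", f))
  }
  ev <- evaluate_dataset(file.path(td, "pred"), file.path(td, "gt"))
  expect_equal(ev$n_images, 2L)
  expect_equal(names(ev$aggregate),
               c("mDice", "mIOU", "wFb", "Smeasure", "Emax", "MAE"))
  expect_equal(unname(unlist(ev$aggregate[c("mDice", "mIOU", "wFb",
                                            "Smeasure", "Emax")])),
               rep(1, 5), tolerance = 1e-6)
  expect_equal(ev$aggregate$MAE, 0)
  # aggregate is the mean of per-image rows
  expect_equal(ev$aggregate$mDice, mean(ev$per_image$mDice))
  # tidy/glance accessors
  expect_equal(nrow(tidy(ev)), 12L)
  expect_equal(glance(ev)$n_images, 2L)
  # mismatched directories abort with the offending files listed
  file.remove(file.path(td, "pred", "img_2.png"))
  expect_error(evaluate_dataset(file.path(td, "pred"), file.path(td, "gt")),
               "img_2.png")
})
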