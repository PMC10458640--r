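# Hybrid loss: printed-form sums against loop oracles, closed-form spot
# values, structural invariants, and gradient correctness.

test_that("BCE matches the per-pixel loop oracle on random pairs", {
  set.seed(10)
  for (k in 1:100) {
    pr <- random_pair(8L)
    expect_lt(abs(bce_loss(pr$pred, pr$gt, reduction = "sum") -
                    oracle_bce_sum(pr$pred, pr$gt)), 1e-6)
  }
})

test_that("BCE closed-form values: -ln(0.5) for one pixel, ~0 for perfection", {
  expect_equal(bce_loss(matrix(0.5), matrix(1), reduction = "sum"),
               0.693147, tolerance = 1e-6)
  gt <- blob_mask(8L)
  v <- bce_loss(gt, gt, reduction = "sum")
  expect_lte(v, 1e-7 * length(gt) * abs(log(1e-7)))
  expect_gte(v, 0)
})

test_that("IoU loss matches the loop oracle and its closed forms", {
  set.seed(11)
  for (k in 1:100) {
    pr <- random_pair(8L)
    if (sum(pr$gt) == 0) next
    expect_lt(abs(iou_loss(pr$pred, pr$gt, reduction = "sum") -
                    oracle_iou_loss(pr$pred, pr$gt)), 1e-6)
  }
  gt <- blob_mask(8L)
  expect_equal(iou_loss(gt, gt, reduction = "sum"), 0)
  expect_equal(iou_loss(1 - gt, gt, reduction = "sum"), 1)
  # half-foreground 2x2 grid against a constant 0.5 prediction
  gt2 <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(iou_loss(matrix(0.5, 2, 2), gt2, reduction = "sum"),
               1 - 1 / 3, tolerance = 1e-12)
})

test_that("degenerate all-background input returns 0 with a warning", {
  expect_warning(v <- iou_loss(matrix(0, 4, 4), matrix(0, 4, 4),
                               reduction = "sum"), "all-background")
  expect_equal(v, 0)
})

test_that("total = bce + iou exactly, in both reductions", {
  set.seed(12)
  pr <- random_pair(8L)
  for (red in c("sum", "mean")) {
    tl <- total_loss(pr$pred, pr$gt, reduction = red)
    expect_identical(tl$total, tl$bce + tl$iou)
    expect_equal(tl$bce, bce_loss(pr$pred, pr$gt, reduction = red))
    expect_equal(tl$iou, iou_loss(pr$pred, pr$gt, reduction = red))
    expect_gte(tl$iou, 0); expect_lte(tl$iou, 1); expect_gte(tl$bce, 0)
  }
})

test_that("BCE decomposes over pixels; IoU does not; IoU ignores permutation", {
  set.seed(13)
  pr <- random_pair(8L)
  top <- 1:4; bot <- 5:8
  b_split <- bce_loss(pr$pred[top, ], pr$gt[top, ], reduction = "sum") +
    bce_loss(pr$pred[bot, ], pr$gt[bot, ], reduction = "sum")
  expect_equal(b_split, bce_loss(pr$pred, pr$gt, reduction = "sum"),
               tolerance = 1e-10)
  i_split <- iou_loss(pr$pred[top, ], pr$gt[top, ], reduction = "sum") +
    iou_loss(pr$pred[bot, ], pr$gt[bot, ], reduction = "sum")
  expect_gt(abs(i_split - iou_loss(pr$pred, pr$gt, reduction = "sum")), 1e-6)
  perm <- sample(64L)
  expect_equal(iou_loss(matrix(pr$pred[perm], 8), matrix(pr$gt[perm], 8),
                        reduction = "sum"),
               iou_loss(pr$pred, pr$gt, reduction = "sum"), tolerance = 1e-12)
})

test_that("both losses fall as the prediction moves toward the truth", {
  set.seed(14)
  pr <- random_pair(8L)
  lambdas <- seq(0, 1, by = 0.25)
  bces <- ious <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    blend <- (1 - lambdas[i]) * pr$pred + lambdas[i] * pr$gt
    bces[i] <- bce_loss(blend, pr$gt, reduction = "sum")
    ious[i] <- iou_loss(blend, pr$gt, reduction = "sum")
  }
  expect_true(all(diff(bces) <= 1e-10))
  expect_true(all(diff(ious) <= 1e-10))
})

test_that("the training-path gradient of the total loss is the sum of component gradients", {
  ad <- asNamespace("mmnet")
  set.seed(15)
  pr <- random_pair(8L)
  pred <- array(pr$pred, c(1L, 8L, 8L, 1L))
  gt <- array(pr$gt, c(1L, 8L, 8L, 1L))
  grad_of <- function(op) {
    t <- ad$new_tensor(pred, requires_grad = TRUE)
    ad$backward(op(t, gt, "mean"))
    t$grad
  }
  g_b <- grad_of(ad$op_bce_loss)
  g_i <- grad_of(ad$op_iou_loss)
  g_t <- grad_of(ad$op_total_loss)
  expect_tensor_close(g_t, g_b + g_i, 1e-12)
  # finite differences at 5 random pixels
  idx <- sample(length(pred), 5L)
  eps <- 1e-6
  for (i in idx) {
    pp <- pred; pp[i] <- pred[i] + eps
    pm <- pred; pm[i] <- pred[i] - eps
    num <- (total_loss(pp, gt)$total - total_loss(pm, gt)$total) / (2 * eps)
    expect_lt(abs(num - g_t[i]), 1e-4)
  }
})

test_that("hard-pixel weighting increases boundary cost and is off by default", {
  gt <- blob_mask(16L)
  w <- hard_pixel_weights(gt, k = 7L)
  expect_equal(dim(w), dim(gt))
  expect_true(all(w >= 1))
  inside <- w[8, 8]; far <- w[1, 1]
  edge <- w[which(abs(gt - 0.5) < 2)[1]]
  expect_gt(max(w), min(w))   # boundary band is up-weighted
  expect_equal(mmnet_config()$loss$weighted, FALSE)
})
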