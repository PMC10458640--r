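# Independent brute-force oracles and small fixtures. Everything here is
# written as plain loops over pixels, independent of the package's
# vectorized / compiled implementations.

oracle_bce_sum <- function(pred, gt, eps = 1e-7) {
  s <- 0
  for (i in seq_along(pred)) {
    p <- min(max(pred[i], eps), 1 - eps)
    s <- s - (gt[i] * log(p) + (1 - gt[i]) * log(1 - p))
  }
  s
}

oracle_iou_loss <- function(pred, gt) {
  num <- 0; den <- 0
  for (i in seq_along(pred)) {
    num <- num + gt[i] * pred[i]
    den <- den + gt[i] + pred[i] - gt[i] * pred[i]
  }
  1 - num / den
}

oracle_dice <- function(pred, gt, threshold = 0.5) {
  tp <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] >= threshold; g <- gt[i] >= 0.5
    if (p && g) tp <- tp + 1
    if (p && !g) fp <- fp + 1
    if (!p && g) fn <- fn + 1
  }
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

oracle_iou <- function(pred, gt, threshold = 0.5) {
  tp <- un <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] >= threshold; g <- gt[i] >= 0.5
    if (p && g) tp <- tp + 1
    if (p || g) un <- un + 1
  }
  if (un == 0) return(1)
  tp / un
}

oracle_mae <- function(pred, gt) {
  s <- 0
  for (i in seq_along(pred)) s <- s + abs(pred[i] - gt[i])
  s / length(pred)
}

# straightforward independent E-measure (enhanced alignment), single threshold
oracle_e_measure <- function(fm, gt) {
  n <- length(gt)
  if (sum(gt) == 0) {
    enh <- 1 - fm
  } else if (sum(gt) == n) {
    enh <- fm
  } else {
    mf <- mean(fm); mg <- mean(gt)
    enh <- numeric(n)
    for (i in seq_len(n)) {
      df <- fm[i] - mf; dg <- gt[i] - mg
      al <- 2 * dg * df / (dg^2 + df^2 + .Machine$double.eps)
      enh[i] <- (al + 1)^2 / 4
    }
  }
  min(1, sum(enh) / (n - 1 + .Machine$double.eps))
}

oracle_e_measure_max <- function(pred, gt, n_th = 256L) {
  best <- 0
  for (t in seq(0, 1, length.out = n_th)) {
    best <- max(best, oracle_e_measure(as.numeric(pred >= t), gt))
  }
  best
}

random_pair <- function(h = 8L, w = h) {
  list(pred = matrix(runif(h * w), h, w),
       gt = matrix(rbinom(h * w, 1, 0.4), h, w))
}

# a blob-like binary mask for metric tests (not all-empty / all-full)
blob_mask <- function(h = 16L, w = h, cx = w / 2, cy = h / 2, r = h / 4) {
  outer(seq_len(h), seq_len(w), function(y, x) ((x - cx)^2 + (y - cy)^2) <= r^2) * 1
}

tiny_synth_dir <- function(n = 8L, seed = 7L, size = 96L,
                           area = c(0.05, 0.15)) {
  d <- file.path(tempdir(), sprintf("synthds_%d_%d_%d", n, seed, size))
  if (!dir.exists(d)) {
    generate_dataset(synthetic_params(image_size = size, n_blobs = c(1L, 2L),
                                      blob_area_fraction = area, seed = seed),
                     n, d)
  }
  d
}

expect_tensor_close <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a - b)), tol)
}
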