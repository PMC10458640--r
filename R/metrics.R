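# Evaluation metrics for binary segmentation against saliency-style ground
# truth: mean Dice, mean IoU, weighted F-beta (spatially weighted
# precision/recall with distance-dependent error weighting), S-measure
# (object- plus region-aware structural similarity), max E-measure
# (enhanced alignment over 256 binarization thresholds) and MAE.
# Report columns follow the customary benchmark ordering:
# mDice, mIOU, wFb, Smeasure, Emax, MAE.

METRIC_EPS <- .Machine$double.eps

check_metric_pair <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) {
    stop("`pred` and `gt` shapes differ", call. = FALSE)
  }
}

#' Dice coefficient of a thresholded prediction
#'
#' @param pred probability matrix `(H, W)`
#' @param gt binary matrix
#' @param threshold binarization threshold on `pred` (default 0.5)
#' @return value in `[0, 1]`; 1 when both masks are empty
#' @export
dice <- function(pred, gt, threshold = 0.5) {
  check_metric_pair(pred, gt)
  p <- pred >= threshold
  g <- gt >= 0.5
  tp <- sum(p & g)
  denom <- 2 * tp + sum(p & !g) + sum(!p & g)
  if (denom == 0) return(1)
  2 * tp / denom
}

#' Intersection-over-union of a thresholded prediction
#' @inheritParams dice
#' @return value in `[0, 1]`; 1 when both masks are empty
#' @export
iou_metric <- function(pred, gt, threshold = 0.5) {
  check_metric_pair(pred, gt)
  p <- pred >= threshold
  g <- gt >= 0.5
  un <- sum(p | g)
  if (un == 0) return(1)
  sum(p & g) / un
}

#' Mean absolute error between a probability map and a binary mask
#' @inheritParams dice
#' @export
mae <- function(pred, gt) {
  check_metric_pair(pred, gt)
  mean(abs(pred - gt))
}

gaussian_kernel <- function(size = 7L, sigma = 5) {
  h <- (size - 1) / 2
  g <- outer(-h:h, -h:h, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g / sum(g)
}

filter2_zero <- function(x, k) {
  H <- nrow(x); W <- ncol(x); ks <- nrow(k)
  xa <- array(x, dim = c(1L, H, W, 1L))
  wa <- array(t(k), dim = c(1L, ks, ks, 1L))  # kernel symmetric here anyway
  p <- (ks - 1L) %/% 2L
  y <- .conv2d_fw(xa, dim(xa), wa, dim(wa), numeric(0), FALSE,
                  1L, 1L, p, p, p, p, 1L, 1L, 1L)
  matrix(y, H, W)
}

#' Weighted F-measure
#'
#' Spatially weighted precision and recall: prediction errors at background
#' pixels inherit the error of the nearest foreground pixel after Gaussian
#' smoothing, and are discounted with distance from the object, so mistakes
#' near the boundary cost more than remote ones.
#' @inheritParams dice
#' @param beta2 relative weight of recall (`beta^2`, default 1)
#' @param sigma,ksize Gaussian smoothing of the propagated errors
#' @return value in `[0, 1]`, or `NA` (with a warning) for empty ground truth
#' @export
weighted_fmeasure <- function(pred, gt, beta2 = 1, sigma = 5, ksize = 7L) {
  check_metric_pair(pred, gt)
  g <- gt >= 0.5
  if (!any(g)) {
    warning("weighted F-measure is undefined for empty ground truth; NA returned")
    return(NA_real_)
  }
  E <- abs(pred - as.numeric(g))
  ed <- .edt_nearest(matrix(as.integer(g), nrow(g)), nrow(g), ncol(g))
  Et <- E
  Et[!g] <- E[ed$index[!g]]
  EA <- filter2_zero(Et, gaussian_kernel(ksize, sigma))
  minEA <- E
  sel <- g & (EA < E)
  minEA[sel] <- EA[sel]
  B <- matrix(1, nrow(g), ncol(g))
  B[!g] <- 2 - exp(log(0.5) / 5 * ed$dist[!g])
  Ew <- minEA * B
  tpw <- sum(g) - sum(Ew[g])
  fpw <- sum(Ew[!g])
  Rw <- 1 - mean(Ew[g])
  Pw <- tpw / (METRIC_EPS + tpw + fpw)
  (1 + beta2) * Rw * Pw / (METRIC_EPS + Rw + beta2 * Pw)
}

ssim_region <- function(p, g) {
  n <- length(p)
  x <- mean(p); y <- mean(g)
  if (n == 1) { sx <- sy <- sxy <- 0 } else {
    sx <- stats::var(as.vector(p))
    sy <- stats::var(as.vector(g))
    sxy <- stats::cov(as.vector(p), as.vector(g))
  }
  a <- 4 * x * y * sxy
  b <- (x^2 + y^2) * (sx + sy)
  if (a != 0) a / (b + METRIC_EPS) else if (b == 0) 1 else 0
}

s_object_term <- function(vals) {
  x <- mean(vals)
  sx <- if (length(vals) > 1) stats::sd(vals) else 0
  2 * x / (x^2 + 1 + sx + METRIC_EPS)
}

#' S-measure (structural similarity of a prediction and a binary mask)
#'
#' Blends an object-aware term (foreground/background value statistics) and a
#' region-aware term (SSIM-like scores in the four quadrants around the
#' ground-truth centroid). All-foreground / all-background ground truths fall
#' back to the mean prediction conventions of the reference definition.
#' @inheritParams dice
#' @param alpha weight of the object term (default 0.5)
#' @return value in `[0, 1]`
#' @export
s_measure <- function(pred, gt, alpha = 0.5) {
  check_metric_pair(pred, gt)
  g <- gt >= 0.5
  u <- mean(g)
  if (u == 0) return(max(0, 1 - mean(pred)))
  if (u == 1) return(max(0, mean(pred)))
  # object-aware
  fg <- pred; fg[!g] <- 0
  bg <- 1 - pred; bg[g] <- 0
  s_o <- u * s_object_term(fg[g]) + (1 - u) * s_object_term(bg[!g])
  # region-aware: split at the foreground centroid
  H <- nrow(g); W <- ncol(g)
  idx <- which(g, arr.ind = TRUE)
  cy <- round(mean(idx[, 1])); cx <- round(mean(idx[, 2]))
  rows1 <- seq_len(cy); rows2 <- setdiff(seq_len(H), rows1)
  cols1 <- seq_len(cx); cols2 <- setdiff(seq_len(W), cols1)
  quads <- list(list(rows1, cols1), list(rows1, cols2),
                list(rows2, cols1), list(rows2, cols2))
  s_r <- 0
  for (q in quads) {
    if (!length(q[[1]]) || !length(q[[2]])) next
    pq <- pred[q[[1]], q[[2]], drop = FALSE]
    gq <- g[q[[1]], q[[2]], drop = FALSE]
    w <- length(pq) / (H * W)
    s_r <- s_r + w * ssim_region(pq, as.numeric(gq))
  }
  max(0, alpha * s_o + (1 - alpha) * s_r)
}

e_measure_single <- function(fm, g) {
  n <- length(g)
  if (sum(g) == 0) {
    enhanced <- 1 - fm
  } else if (sum(g) == n) {
    enhanced <- fm
  } else {
    dg <- g - mean(g)
    df <- fm - mean(fm)
    align <- 2 * dg * df / (dg^2 + df^2 + METRIC_EPS)
    enhanced <- (align + 1)^2 / 4
  }
  # the n-1 normalization can nominally exceed 1 on exact agreement at small
  # n; the score is defined on [0, 1]
  min(1, sum(enhanced) / (n - 1 + METRIC_EPS))
}

#' Max E-measure (enhanced-alignment measure over thresholds)
#'
#' The prediction is binarized at 256 uniform thresholds; each binary map is
#' scored by the enhanced-alignment statistic (pixel-level agreement of
#' mean-centred maps, rewarding joint deviation), and the maximum over
#' thresholds is returned.
#' @inheritParams dice
#' @param n_thresholds number of uniform thresholds in `[0, 1]`
#' @return value in `[0, 1]`
#' @export
e_measure_max <- function(pred, gt, n_thresholds = 256L) {
  check_metric_pair(pred, gt)
  g <- as.numeric(gt >= 0.5)
  ths <- seq(0, 1, length.out = n_thresholds)
  best <- 0
  for (t in ths) {
    fm <- as.numeric(pred >= t)
    best <- max(best, e_measure_single(fm, g))
  }
  best
}

#' All six metrics for one prediction/ground-truth pair
#' @inheritParams dice
#' @return named numeric vector `(mDice, mIOU, wFb, Smeasure, Emax, MAE)`
#' @export
evaluate_pair <- function(pred, gt, threshold = 0.5) {
  c(mDice = dice(pred, gt, threshold),
    mIOU = iou_metric(pred, gt, threshold),
    wFb = weighted_fmeasure(pred, gt),
    Smeasure = s_measure(pred, gt),
    Emax = e_measure_max(pred, gt),
    MAE = mae(pred, gt))
}

#' Evaluate a directory of predictions against ground-truth masks
#'
#' Files are matched by name; predictions are 8-bit grayscale probability
#' maps, ground-truth masks are binarized at 128/255.
#' @param pred_dir,gt_dir directories of PNG files with matching names
#' @param threshold binarization threshold for Dice/IoU
#' @return an `mmnet_eval` object: `per_image` tibble (one row per image) and
#'   `aggregate` tibble of metric means; `tidy()`, `glance()` and
#'   `autoplot()` methods apply
#' @export
evaluate_dataset <- function(pred_dir, gt_dir, threshold = 0.5) {
  pf <- sort(list.files(pred_dir, pattern = "\\.png$"))
  gf <- sort(list.files(gt_dir, pattern = "\\.png$"))
  if (!length(gf)) stop("no PNG masks found in ", gt_dir, call. = FALSE)
  missing_pred <- setdiff(gf, pf)
  missing_gt <- setdiff(pf, gf)
  if (length(missing_pred) || length(missing_gt)) {
    stop("file mismatch between prediction and ground-truth directories:\n",
         if (length(missing_pred))
           paste0("  missing predictions: ", paste(missing_pred, collapse = ", "), "\n"),
         if (length(missing_gt))
           paste0("  missing masks: ", paste(missing_gt, collapse = ", ")),
         call. = FALSE)
  }
  rows <- purrr::map(gf, function(f) {
    pred <- read_gray_png(file.path(pred_dir, f))
    gt <- read_mask_png(file.path(gt_dir, f))
    m <- evaluate_pair(pred, gt, threshold)
    tibble::tibble(image = f, !!!as.list(m))
  })
  per_image <- dplyr::bind_rows(rows)
  aggregate <- per_image |>
    dplyr::summarise(dplyr::across(
      c("mDice", "mIOU", "wFb", "Smeasure", "Emax", "MAE"),
      ~ mean(.x, na.rm = TRUE)))
  structure(list(per_image = per_image, aggregate = aggregate,
                 n_images = nrow(per_image), threshold = threshold),
            class = "mmnet_eval")
}

#' @export
print.mmnet_eval <- function(x, ...) {
  cat(sprintf("<mmnet_eval> %d images (threshold %.2f)\n", x$n_images, x$threshold))
  print(as.data.frame(x$aggregate), row.names = FALSE, digits = 4)
  invisible(x)
}
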