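# Hybrid segmentation objective: pixel-wise binary cross-entropy plus soft
# intersection-over-union.
#
#   L_BCE = -sum[ R log(Rhat) + (1 - R) log(1 - Rhat) ]
#   L_IOU = 1 - sum(R * Rhat) / sum(R + Rhat - R * Rhat)
#   L_total = L_BCE + L_IOU
#
# The printed forms are sums/global ratios (`reduction = "sum"`); for
# optimization the default is the conventional scaling: BCE averaged per
# pixel and the IoU ratio taken per image then averaged over the batch.

LOSS_EPS <- 1e-7

check_loss_pair <- function(pred, gt) {
  if (!identical(dim(pred) %||% length(pred), dim(gt) %||% length(gt))) {
    stop("`pred` and `gt` shapes differ", call. = FALSE)
  }
  if (!all(gt %in% c(0, 1))) {
    stop("`gt` must be binary {0, 1}", call. = FALSE)
  }
}

clamp01 <- function(p, eps = LOSS_EPS) pmin(pmax(p, eps), 1 - eps)

# per-image grouping: everything except the last dim if 4D, else one image
split_images <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 4L) return(list(as.vector(x)))
  n <- d[length(d)]
  m <- matrix(x, ncol = n)
  lapply(seq_len(n), function(i) m[, i])
}

#' Binary cross-entropy loss
#'
#' @param pred probability map (any shape; a 4th dimension indexes images)
#' @param gt matching binary map
#' @param reduction `"mean"` (per-pixel mean, default) or `"sum"` (the raw
#'   summed form)
#' @param weights optional per-pixel weight map (hard-pixel weighting)
#' @return nonnegative scalar
#' @export
bce_loss <- function(pred, gt, reduction = c("mean", "sum"), weights = NULL) {
  reduction <- match.arg(reduction)
  check_loss_pair(pred, gt)
  p <- clamp01(pred)
  w <- weights %||% 1
  ll <- -w * (gt * log(p) + (1 - gt) * log(1 - p))
  if (reduction == "sum") sum(ll) else sum(ll) / sum(w * rep(1, length(ll)))
}

#' Soft intersection-over-union loss
#'
#' @inheritParams bce_loss
#' @param reduction `"mean"` (ratio per image, averaged over the batch) or
#'   `"sum"` (one global ratio over all pixels, the printed form)
#' @return value in `[0, 1]`
#' @export
iou_loss <- function(pred, gt, reduction = c("mean", "sum"), weights = NULL) {
  reduction <- match.arg(reduction)
  check_loss_pair(pred, gt)
  ratio <- function(p, g, w) {
    num <- sum(w * g * p)
    den <- sum(w * (g + p - g * p))
    if (den == 0) {
      warning("all-background ground truth with an all-zero prediction; ",
              "IoU loss taken as 0 by convention")
      return(0)
    }
    1 - num / den
  }
  if (reduction == "sum") {
    ratio(as.vector(pred), as.vector(gt), weights %||% 1)
  } else {
    ps <- split_images(pred); gs <- split_images(gt)
    ws <- if (is.null(weights)) rep(list(1), length(ps)) else split_images(weights)
    mean(mapply(ratio, ps, gs, ws))
  }
}

#' Total hybrid loss (BCE + IoU)
#'
#' @inheritParams bce_loss
#' @param reduction passed to both components
#' @return an `mmnet_loss` list with fields `bce`, `iou`, `total`
#'   (`total == bce + iou` exactly)
#' @export
total_loss <- function(pred, gt, reduction = c("mean", "sum"), weights = NULL) {
  reduction <- match.arg(reduction)
  b <- bce_loss(pred, gt, reduction, weights)
  i <- iou_loss(pred, gt, reduction, weights)
  structure(list(bce = b, iou = i, total = b + i), class = "mmnet_loss")
}

#' @export
print.mmnet_loss <- function(x, ...) {
  cat(sprintf("hybrid loss: total %.6f (bce %.6f + iou %.6f)\n",
              x$total, x$bce, x$iou))
  invisible(x)
}

#' Hard-pixel weight map (boundary-emphasising)
#'
#' `1 + 5 * |boxblur(gt, 31) - gt|`: pixels whose neighbourhood disagrees
#' with their own label (boundaries, small structures) weigh more. Off by
#' default in the training objective.
#' @param gt binary array `(H, W[, 1, N])`
#' @param k box size (odd)
#' @return weight array of `gt`'s shape
#' @export
hard_pixel_weights <- function(gt, k = 31L) {
  d <- dim(gt)
  if (length(d) == 2L) dim(gt) <- c(1L, d, 1L)
  else if (length(d) == 3L) dim(gt) <- c(1L, d)   # (H,W,N)
  # length 4: already (1,H,W,N)
  w <- array(1 / k^2, dim = c(1L, k, k, 1L))
  p <- (k - 1L) %/% 2L
  blur <- .conv2d_fw(gt, dim(gt), w, dim(w), numeric(0), FALSE,
                     1L, 1L, p, p, p, p, 1L, 1L, 1L)
  out <- 1 + 5 * abs(blur - gt)
  dim(out) <- d
  out
}

# --- autodiff versions (training path) --------------------------------------

op_bce_loss <- function(pred, gt, reduction = "mean", weights = NULL) {
  pred <- as_tensor(pred)
  p_raw <- pred$value
  p <- clamp01(p_raw)
  inside <- (p_raw > LOSS_EPS) & (p_raw < 1 - LOSS_EPS)
  w <- weights %||% 1
  ll <- -w * (gt * log(p) + (1 - gt) * log(1 - p))
  norm <- if (reduction == "sum") 1 else length(ll)
  val <- sum(ll) / norm
  new_tensor(array(val, 1L), parents = list(pred), backward = function(g) {
    dp <- w * (p - gt) / (p * (1 - p)) * inside / norm
    list(array(as.numeric(g) * dp, dim = dim(p_raw)))
  })
}

op_iou_loss <- function(pred, gt, reduction = "mean", weights = NULL) {
  pred <- as_tensor(pred)
  p <- pred$value
  d <- dim(p)
  n_img <- if (reduction == "sum" || length(d) < 4L) 1L else d[length(d)]
  w <- weights %||% array(1, dim = d %||% length(p))
  if (length(w) == 1L) w <- array(w, dim = d %||% length(p))
  pm <- matrix(p, ncol = n_img); gm <- matrix(gt, ncol = n_img)
  wm <- matrix(w, ncol = n_img)
  I <- colSums(wm * gm * pm)
  U <- colSums(wm * (gm + pm - gm * pm))
  li <- ifelse(U == 0, 0, 1 - I / U)
  val <- mean(li)
  new_tensor(array(val, 1L), parents = list(pred), backward = function(g) {
    dpm <- matrix(0, nrow(pm), n_img)
    for (i in seq_len(n_img)) {
      if (U[i] == 0) next
      dpm[, i] <- -wm[, i] * (gm[, i] * U[i] - I[i] * (1 - gm[, i])) / U[i]^2
    }
    list(array(as.numeric(g) * dpm / n_img, dim = d %||% length(p)))
  })
}

op_total_loss <- function(pred, gt, reduction = "mean", weights = NULL) {
  op_add(op_bce_loss(pred, gt, reduction, weights),
         op_iou_loss(pred, gt, reduction, weights))
}
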