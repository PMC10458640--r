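# Training and inference: seeded training loop with the published recipe
# (Adam, polynomial learning-rate decay, multi-scale batches, geometric
# augmentation), checkpointing with exact forward reproducibility, and
# directory-level prediction.

#' Polynomial learning-rate schedule
#'
#' `"poly"` (default): `base_lr * (1 - epoch/epochs)^power`. `"step"`:
#' `base_lr * factor^floor(epoch / (epochs/3))`, the staircase reading of a
#' decay "factor".
#' @param epoch 0-based epoch
#' @param cfg an `mmnet_config` (uses `train$base_lr`, `train$epochs`,
#'   `train$lr_decay`)
#' @return the learning rate, positive for `epoch < epochs`
#' @export
lr_at <- function(epoch, cfg) {
  tr <- cfg$train
  dk <- tr$lr_decay
  if (identical(dk$kind, "step")) {
    steps <- floor(epoch / max(1, tr$epochs / 3))
    return(tr$base_lr * dk$factor^steps)
  }
  tr$base_lr * (1 - epoch / tr$epochs)^(dk$power %||% 0.9)
}

#' Rescale a batch for multi-scale training
#'
#' Images are rescaled bilinearly and masks by nearest neighbour to
#' `round(size * factor)` snapped *up* to the next multiple of 32 (the
#' backbone stride contract).
#' @param images array `(H, W, 3, N)`; @param masks array `(H, W, N)` or NULL
#' @param factor scale factor
#' @param base_size the nominal training size (defaults to `H`)
#' @return list `(images, masks, size)`
#' @export
multiscale_batch <- function(images, masks = NULL, factor = 1,
                             base_size = dim(images)[1]) {
  size <- snap32(round(base_size * factor))
  if (size == dim(images)[1] && size == dim(images)[2]) {
    return(list(images = images, masks = masks, size = size))
  }
  N <- dim(images)[4]
  oi <- array(0, dim = c(size, size, 3L, N))
  om <- if (!is.null(masks)) array(0, dim = c(size, size, N))
  for (n in seq_len(N)) {
    oi[, , , n] <- resize_image(images[, , , n], c(size, size), "bilinear")
    if (!is.null(masks)) {
      om[, , n] <- resize_image(masks[, , n], c(size, size), "nearest")
    }
  }
  list(images = oi, masks = om, size = size)
}

snap32 <- function(s) 32L * as.integer(ceiling(s / 32))

# inverse-mapped affine resample of (H,W[,C]) about the image center
affine_sample <- function(img, angle_deg = 0, zoom = 1,
                          method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(img)
  H <- d[1]; W <- d[2]
  chans <- if (length(d) == 3L) d[3] else 1L
  if (length(d) == 2L) dim(img) <- c(d, 1L)
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(rep(seq_len(W), each = H), H, W) - cx
  # inverse transform: rotate by -th, scale by 1/zoom
  sx <- (cos(th) * xx + sin(th) * yy) / zoom + cx
  sy <- (-sin(th) * xx + cos(th) * yy) / zoom + cy
  out <- array(0, dim = c(H, W, chans))
  if (method == "nearest") {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    idx <- cbind(ri[ok], ci[ok])
    for (c in seq_len(chans)) {
      ch <- matrix(0, H, W)
      ch[ok] <- img[, , c][idx]
      out[, , c] <- ch
    }
  } else {
    r0 <- floor(sy); c0 <- floor(sx)
    fr <- sy - r0; fc <- sx - c0
    for (c in seq_len(chans)) {
      plane <- img[, , c]
      val <- matrix(0, H, W)
      for (dr in 0:1) for (dc in 0:1) {
        rr <- r0 + dr; cc <- c0 + dc
        ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
        contrib <- matrix(0, H, W)
        contrib[ok] <- plane[cbind(rr[ok], cc[ok])]
        val <- val + w * contrib
      }
      out[, , c] <- val
    }
  }
  if (length(d) == 2L) dim(out) <- c(H, W)
  out
}

#' Random geometric augmentation of one image/mask pair
#'
#' The same transform is applied to image (bilinear) and mask (nearest
#' neighbour), so pixel correspondence is preserved and the mask stays
#' binary: optional horizontal/vertical flips, rotation up to the configured
#' maximum (default 90 degrees either way), and a random zoom.
#' @param sample list with `image` `(H, W, 3)` and binary `mask` `(H, W)`
#' @param cfg the `train$augment` sub-config
#' @return transformed sample (same shapes), with the drawn transform in
#'   `$transform`
#' @export
augment <- function(sample, cfg = mmnet_config()$train$augment) {
  tr <- list(hflip = FALSE, vflip = FALSE, angle = 0, zoom = 1)
  if (isTRUE(cfg$hflip) && stats::runif(1) < 0.5) tr$hflip <- TRUE
  if (isTRUE(cfg$vflip) && stats::runif(1) < 0.5) tr$vflip <- TRUE
  if ((cfg$rotate_max_deg %||% 0) > 0 && stats::runif(1) < 0.5) {
    tr$angle <- stats::runif(1, -cfg$rotate_max_deg, cfg$rotate_max_deg)
  }
  if (!is.null(cfg$rescale) && stats::runif(1) < 0.5) {
    tr$zoom <- stats::runif(1, cfg$rescale[1], cfg$rescale[2])
  }
  img <- sample$image; msk <- sample$mask
  if (tr$hflip) { img <- img[, rev(seq_len(ncol(msk))), , drop = FALSE]
                  msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE] }
  if (tr$vflip) { img <- img[rev(seq_len(nrow(msk))), , , drop = FALSE]
                  msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE] }
  if (tr$angle != 0 || tr$zoom != 1) {
    img <- affine_sample(img, tr$angle, tr$zoom, "bilinear")
    msk <- affine_sample(msk, tr$angle, tr$zoom, "nearest")
  }
  list(image = img, mask = msk, transform = tr)
}

# --- dataset loading --------------------------------------------------------

#' Load an image/mask directory pair (benchmark layout) into memory
#'
#' Expects `dir/images/*` and `dir/masks/*.png` with matching names; images
#' are resized bilinearly to `size`, masks by nearest neighbour.
#' @param dir dataset directory
#' @param size target square size (must divide by 32 for training)
#' @return list of samples, each `(image, mask, file)`
#' @export
load_dataset_dir <- function(dir, size = 352L) {
  imgs <- sort(list.files(file.path(dir, "images"),
                          pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE))
  if (!length(imgs)) stop("no images found under ", dir, call. = FALSE)
  lapply(imgs, function(f) {
    mask_f <- file.path(dir, "masks", paste0(tools::file_path_sans_ext(f), ".png"))
    if (!file.exists(mask_f)) stop("missing mask for image ", f, call. = FALSE)
    img <- resize_image(read_image(file.path(dir, "images", f)),
                        c(size, size), "bilinear")
    msk <- resize_image(read_mask_png(mask_f), c(size, size), "nearest")
    list(image = img, mask = msk, file = f)
  })
}

stack_batch <- function(samples) {
  H <- nrow(samples[[1]]$mask); W <- ncol(samples[[1]]$mask)
  N <- length(samples)
  imgs <- array(0, dim = c(H, W, 3L, N))
  msks <- array(0, dim = c(H, W, N))
  for (i in seq_len(N)) {
    imgs[, , , i] <- samples[[i]]$image
    msks[, , i] <- samples[[i]]$mask
  }
  list(images = imgs, masks = msks)
}

batch_dice <- function(prob, masks, threshold = 0.5) {
  N <- dim(masks)[3] %||% 1L
  if (length(dim(masks)) == 2L) {
    return(dice(prob, masks, threshold))
  }
  mean(vapply(seq_len(N), function(i) dice(prob[, , i], masks[, , i], threshold),
              numeric(1)))
}

# --- training ---------------------------------------------------------------

#' Train an MMNet model
#'
#' Fully seeded (weights, shuffling, augmentation, multi-scale draws). Logs
#' per-iteration loss and per-epoch train/validation Dice; retains the
#' checkpoint with the best validation Dice.
#' @param config an [mmnet_config()]
#' @param train_dir,val_dir dataset directories in the `images/` + `masks/`
#'   layout (`val_dir` may equal `train_dir` for smoke runs)
#' @param model optionally, an already-built model to continue training
#' @param quiet suppress progress output
#' @return an `mmnet_fit`: `model`, `log` (tibble), `best` checkpoint,
#'   `config`; `tidy()`/`glance()`/`autoplot()` apply
#' @export
mmnet_train <- function(config, train_dir, val_dir = train_dir, model = NULL,
                        quiet = FALSE) {
  tr <- config$train
  set.seed(as.integer(config$seed))
  if (is.null(model)) model <- build_mmnet(config, seed = config$seed)
  data <- load_dataset_dir(train_dir, config$image_size)
  if (!length(data)) stop("empty training dataset", call. = FALSE)
  val <- if (identical(val_dir, train_dir)) data else
    load_dataset_dir(val_dir, config$image_size)
  opt <- adam_new(model$ps$params)
  weighted <- isTRUE(config$loss$weighted)
  steps_per_epoch <- max(1L, ceiling(length(data) / tr$batch_size))
  total_iters <- tr$max_iterations %||% (tr$epochs * steps_per_epoch)
  log_rows <- vector("list", 0L)
  best <- list(dice = -Inf, checkpoint = NULL, epoch = NA_integer_)
  it <- 0L
  epoch <- 0L
  while (it < total_iters) {
    ord <- sample.int(length(data))
    lr <- lr_at(min(epoch, tr$epochs - 1L), config)
    epoch_losses <- c()
    for (bs in seq_len(steps_per_epoch)) {
      if (it >= total_iters) break
      idx <- ord[((bs - 1L) * tr$batch_size + 1L):
                   min(bs * tr$batch_size, length(data))]
      batch_samples <- data[idx]
      if (isTRUE(tr$augment$enabled)) {
        batch_samples <- lapply(batch_samples, augment, cfg = tr$augment)
      }
      b <- stack_batch(batch_samples)
      f <- if (length(tr$multiscale_factors) > 1L) {
        tr$multiscale_factors[sample.int(length(tr$multiscale_factors), 1L)]
      } else tr$multiscale_factors[1]
      b <- multiscale_batch(b$images, b$masks, f, base_size = config$image_size)
      gt <- b$masks
      dim(gt) <- c(1L, dim(gt)[1], dim(gt)[2], dim(gt)[3])
      w <- if (weighted) hard_pixel_weights(gt) else NULL
      zero_grads(model$ps$params)
      prob <- model$forward(b$images, training = TRUE)
      loss <- op_total_loss(prob, gt, reduction = config$loss$reduction,
                            weights = w)
      if (!is.finite(loss$value)) stop("non-finite loss at iteration ", it)
      backward(loss)
      adam_step(opt, model$ps$params, lr)
      it <- it + 1L
      epoch_losses <- c(epoch_losses, as.numeric(loss$value))
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        iteration = it, epoch = epoch, lr = lr,
        loss = as.numeric(loss$value), phase = "train_step")
    }
    # end-of-epoch evaluation on train and val (forward in eval mode),
    # every `val_every` epochs and always on the final epoch
    epoch <- epoch + 1L
    eval_now <- (epoch %% (tr$val_every %||% 1L) == 0L) || it >= total_iters
    train_d <- if (eval_now) dataset_dice(model, data, config) else NA_real_
    val_d <- if (!eval_now) NA_real_ else if (identical(val_dir, train_dir))
      train_d else dataset_dice(model, val, config)
    log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
      iteration = it, epoch = epoch, lr = lr,
      loss = mean(epoch_losses), phase = "epoch",
      train_dice = train_d, val_dice = val_d)
    if (!quiet) {
      message(sprintf("epoch %d (iter %d): loss %.4f train dice %.4f val dice %.4f",
                      epoch, it, mean(epoch_losses), train_d, val_d))
    }
    if (!is.na(val_d) && val_d > best$dice) {
      best <- list(dice = val_d, epoch = epoch,
                   checkpoint = checkpoint_state(model, epoch))
    }
  }
  log <- dplyr::bind_rows(log_rows)
  structure(list(model = model, log = log, best = best, config = config),
            class = "mmnet_fit")
}

dataset_dice <- function(model, data, config, threshold = 0.5) {
  b <- stack_batch(data)
  prob <- mmnet_forward(model, b$images, training = FALSE)
  if (length(dim(prob)) == 2L) dim(prob) <- c(dim(prob), 1L)
  batch_dice(prob, b$masks, threshold)
}

#' @export
print.mmnet_fit <- function(x, ...) {
  ep <- dplyr::filter(x$log, .data$phase == "epoch")
  cat(sprintf("<mmnet_fit> %d iterations, %d epochs; best val dice %.4f (epoch %s)\n",
              max(x$log$iteration), nrow(ep), x$best$dice, x$best$epoch))
  invisible(x)
}

# --- checkpointing ----------------------------------------------------------

checkpoint_state <- function(model, epoch = NA_integer_) {
  list(values = lapply(model$ps$params, function(p) p$value),
       buffers = lapply(model$ps$buffers, function(b) as.list(b)),
       config = model$config, epoch = epoch,
       rng = .Random.seed)
}

#' Save / load a model checkpoint
#'
#' A checkpoint restores weights, batch-norm state, config and RNG state;
#' a reloaded model reproduces the saved model's forward pass bit for bit.
#' @param model an `mmnet_model` (or an `mmnet_fit`, whose best checkpoint is
#'   taken)
#' @param path `.rds` destination
#' @param epoch optional epoch number to record in the checkpoint
#' @export
save_checkpoint <- function(model, path, epoch = NA_integer_) {
  st <- if (inherits(model, "mmnet_fit")) model$best$checkpoint
        else checkpoint_state(model, epoch)
  saveRDS(st, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param restore_rng restore the RNG state stored in the checkpoint
#' @return `load_checkpoint`: an `mmnet_model`
#' @export
load_checkpoint <- function(path, restore_rng = FALSE) {
  st <- readRDS(path)
  model <- build_mmnet(st$config, seed = st$config$seed)
  load_param_values(model$ps, st$values)
  for (nm in names(st$buffers)) {
    for (f in names(st$buffers[[nm]])) {
      model$ps$buffers[[nm]][[f]] <- st$buffers[[nm]][[f]]
    }
  }
  if (restore_rng && !is.null(st$rng)) {
    assign(".Random.seed", st$rng, envir = globalenv())
  }
  model
}

# --- prediction -------------------------------------------------------------

#' Predict masks for a directory of images
#'
#' Each image is resized to the model's input size, passed through the
#' network, and the probability map is resized back to the original
#' dimensions. Writes `<name>.png` (8-bit probability map) into `out_dir`
#' and, when `threshold` is not `NA`, a binary `masks/<name>.png` beneath it;
#' output names mirror input names so either directory can be scored against
#' ground truth with [evaluate_dataset()].
#' @param model an `mmnet_model` or a checkpoint path
#' @param image_dir input images; @param out_dir output directory
#' @param threshold binarization threshold (NA: probabilities only)
#' @return tibble of written files, invisibly
#' @export
mmnet_predict <- function(model, image_dir, out_dir, threshold = 0.5) {
  if (is.character(model)) model <- load_checkpoint(model)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.na(threshold)) {
    dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  }
  size <- model$config$image_size
  files <- sort(list.files(image_dir, pattern = "\\.(png|jpg|jpeg)$",
                           ignore.case = TRUE))
  rows <- purrr::map(files, function(f) {
    img <- read_image(file.path(image_dir, f))
    d0 <- dim(img)[1:2]
    x <- resize_image(img, c(size, size), "bilinear")
    prob <- mmnet_forward(model, x)
    prob <- resize_image(prob, d0, "bilinear")
    base <- tools::file_path_sans_ext(f)
    pp <- file.path(out_dir, paste0(base, ".png"))
    write_mask_png(prob, pp)
    mp <- NA_character_
    if (!is.na(threshold)) {
      mp <- file.path(out_dir, "masks", paste0(base, ".png"))
      write_mask_png((prob >= threshold) * 1, mp)
    }
    tibble::tibble(image = f, prob_png = pp, mask_png = mp)
  })
  invisible(dplyr::bind_rows(rows))
}
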