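# Seeded generator of polyp-like image/mask pairs. Each sample is a smooth
# reddish mucosa-like background carrying one to a few bright, blurred,
# low-contrast elliptical blobs (rotated super-ellipses with irregular radial
# perturbation), specular highlight disks and a multiplicative vignette —
# the statistical skeleton of colonoscopy polyp benchmarks, including the
# very small blob sizes that make some corpora hard. Masks are exact blob
# interiors; only the rendered image is blurred.

#' Parameters of the synthetic polyp generator
#'
#' @param image_size `(H, W)` of generated samples
#' @param n_blobs integer range (min, max) of blobs per image
#' @param blob_area_fraction range of per-blob area as a fraction of the
#'   image, sampled log-uniformly (default 0.002-0.25: very small through
#'   large polyps)
#' @param contrast_delta range of foreground/background intensity gap; the
#'   lower end deliberately approaches 0 so foreground and background
#'   statistics overlap
#' @param blur_sigma range of the Gaussian boundary blur, pixels
#' @param specular_count integer range of specular highlight disks
#' @param vignette_strength multiplicative corner darkening in `[0, 1)`
#' @param noise_sd additive Gaussian pixel noise
#' @param seed integer; with the sample index it fixes every sample bit for bit
#' @param allow_empty permit an empty mask (off: blob placement is retried)
#' @return a `synthetic_params` list
#' @export
synthetic_params <- function(image_size = c(352L, 352L),
                             n_blobs = c(1L, 3L),
                             blob_area_fraction = c(0.002, 0.25),
                             contrast_delta = c(0.02, 0.35),
                             blur_sigma = c(0.5, 2.5),
                             specular_count = c(0L, 6L),
                             vignette_strength = 0.35,
                             noise_sd = 0.02,
                             seed = 1L,
                             allow_empty = FALSE) {
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  stopifnot(all(blob_area_fraction > 0), all(blob_area_fraction < 1),
            diff(range(n_blobs)) >= 0, vignette_strength >= 0,
            vignette_strength < 1)
  structure(list(image_size = as.integer(image_size),
                 n_blobs = as.integer(range(n_blobs)),
                 blob_area_fraction = range(blob_area_fraction),
                 contrast_delta = range(contrast_delta),
                 blur_sigma = range(blur_sigma),
                 specular_count = as.integer(range(specular_count)),
                 vignette_strength = vignette_strength,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 allow_empty = isTRUE(allow_empty)),
            class = "synthetic_params")
}

sample_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

runif1 <- function(rg) stats::runif(1, rg[1], rg[2])
rlogunif1 <- function(rg) exp(stats::runif(1, log(rg[1]), log(rg[2])))

# render one blob's interior on the pixel grid from its meta description
render_blob <- function(meta, H, W) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(rep(seq_len(W), each = H), H, W)
  u <- (xx - meta$cx) * cos(meta$theta) + (yy - meta$cy) * sin(meta$theta)
  v <- -(xx - meta$cx) * sin(meta$theta) + (yy - meta$cy) * cos(meta$theta)
  ang <- atan2(v, u)
  pert <- rep(0, length(ang))
  for (k in seq_along(meta$pert_amp)) {
    pert <- pert + meta$pert_amp[k] * cos((k + 1) * ang + meta$pert_phase[k])
  }
  r <- (abs(u) / meta$a)^meta$expo + (abs(v) / meta$b)^meta$expo
  matrix(r <= (1 + pert)^meta$expo, H, W)
}

#' Re-render the binary mask of a sample from its stored blob metadata
#' @param meta the `meta` field of a [generate_sample()] record (or one
#'   manifest entry)
#' @param image_size `(H, W)`
#' @return binary matrix
#' @export
render_mask <- function(meta, image_size) {
  H <- image_size[1]; W <- image_size[2]
  mask <- matrix(FALSE, H, W)
  for (b in meta$blobs) mask <- mask | render_blob(b, H, W)
  mask * 1
}

smooth_field <- function(H, W, n_waves = 4L, scale = 1) {
  yy <- matrix(seq_len(H) / H, H, W)
  xx <- matrix(rep(seq_len(W) / W, each = H), H, W)
  f <- matrix(0, H, W)
  for (k in seq_len(n_waves)) {
    fx <- stats::runif(1, 0.5, 3); fy <- stats::runif(1, 0.5, 3)
    ph <- stats::runif(2, 0, 2 * pi)
    f <- f + stats::runif(1, 0.2, 1) * sin(2 * pi * fx * xx + ph[1]) *
      sin(2 * pi * fy * yy + ph[2])
  }
  scale * f / n_waves
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  ks <- 2L * ceiling(2.5 * sigma) + 1L
  g <- exp(-((seq_len(ks) - (ks + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  H <- nrow(m); W <- ncol(m)
  xa <- array(m, dim = c(1L, H, W, 1L))
  p <- (ks - 1L) %/% 2L
  kv <- array(g, dim = c(1L, ks, 1L, 1L))
  y <- .conv2d_fw(xa, dim(xa), kv, dim(kv), numeric(0), FALSE,
                  1L, 1L, p, p, 0L, 0L, 1L, 1L, 1L)
  kh <- array(g, dim = c(1L, 1L, ks, 1L))
  y <- .conv2d_fw(y, dim(y), kh, dim(kh), numeric(0), FALSE,
                  1L, 1L, 0L, 0L, p, p, 1L, 1L, 1L)
  matrix(y, H, W)
}

#' Generate one synthetic polyp sample
#'
#' A deterministic function of `(params$seed, index)`.
#' @param params a [synthetic_params()]
#' @param index sample index (0-based or 1-based, any integer)
#' @return a `sample_record`: `image` `(H, W, 3)` in `[0, 1]`, binary `mask`
#'   `(H, W)`, and `meta` (seed, per-blob geometry, contrast, blur) from
#'   which the mask can be re-rendered exactly
#' @export
generate_sample <- function(params, index = 0L) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(sample_seed(params$seed, index))
  H <- params$image_size[1]; W <- params$image_size[2]
  n_target <- if (params$n_blobs[1] == params$n_blobs[2]) params$n_blobs[1] else
    sample(params$n_blobs[1]:params$n_blobs[2], 1L)
  blobs <- list()
  mask <- matrix(FALSE, H, W)
  for (bi in seq_len(n_target)) {
    placed <- FALSE
    for (attempt in seq_len(100L)) {
      frac <- rlogunif1(params$blob_area_fraction)
      area <- frac * H * W
      aspect <- stats::runif(1, 0.55, 1)
      a <- sqrt(area / (pi * aspect))
      b <- a * aspect
      if (2 * a >= min(H, W)) next
      meta <- list(
        cx = stats::runif(1, a + 1, W - a - 1),
        cy = stats::runif(1, a + 1, H - a - 1),
        a = a, b = b,
        theta = stats::runif(1, 0, pi),
        expo = stats::runif(1, 1.8, 3),
        pert_amp = stats::runif(4, 0, 0.06),
        pert_phase = stats::runif(4, 0, 2 * pi),
        area_fraction = frac
      )
      bm <- render_blob(meta, H, W)
      if (!any(bm) && !params$allow_empty) next
      blobs[[length(blobs) + 1L]] <- meta
      mask <- mask | bm
      placed <- TRUE
      break
    }
    if (!placed && !params$allow_empty) {
      stop("could not place blob ", bi, " within 100 attempts ",
           "(image too small for the requested area fraction)", call. = FALSE)
    }
  }
  contrast <- runif1(params$contrast_delta)
  blur <- runif1(params$blur_sigma)
  base <- 0.45 + smooth_field(H, W, scale = 0.35)
  soft <- gaussian_blur(mask * 1, blur)
  fg_tex <- smooth_field(H, W, n_waves = 3L, scale = 0.25)
  lum <- base + contrast * soft + 0.3 * soft * fg_tex
  # reddish mucosa coloring, channels correlated with luminance
  img <- array(0, dim = c(H, W, 3L))
  img[, , 1] <- 0.55 + 0.45 * lum
  img[, , 2] <- 0.25 + 0.40 * lum
  img[, , 3] <- 0.20 + 0.35 * lum
  n_spec <- if (params$specular_count[1] == params$specular_count[2])
    params$specular_count[1] else
    sample(params$specular_count[1]:params$specular_count[2], 1L)
  speculars <- list()
  if (n_spec > 0) {
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(rep(seq_len(W), each = H), H, W)
    for (s in seq_len(n_spec)) {
      sx <- stats::runif(1, 1, W); sy <- stats::runif(1, 1, H)
      sr <- stats::runif(1, 1, 0.02 * min(H, W) + 2)
      glow <- exp(-((xx - sx)^2 + (yy - sy)^2) / (2 * sr^2))
      for (c in 1:3) img[, , c] <- img[, , c] + 0.9 * glow
      speculars[[s]] <- list(x = sx, y = sy, r = sr)
    }
  }
  if (params$vignette_strength > 0) {
    yy <- (matrix(seq_len(H), H, W) - (H + 1) / 2) / (H / 2)
    xx <- (matrix(rep(seq_len(W), each = H), H, W) - (W + 1) / 2) / (W / 2)
    vig <- 1 - params$vignette_strength * pmin(1, (xx^2 + yy^2) / 2)
    for (c in 1:3) img[, , c] <- img[, , c] * vig
  }
  if (params$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim = dim(img))
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(
    image = img,
    mask = mask * 1,
    meta = list(seed = params$seed, index = index, blobs = blobs,
                contrast = contrast, blur = blur, speculars = speculars)
  ), class = "sample_record")
}

#' Generate a dataset of synthetic samples on disk
#'
#' Writes the customary benchmark layout: `images/*.png`, `masks/*.png`
#' (matching names) and a `manifest.json` with per-sample metadata and an
#' index-parity train/test split. Re-running with identical parameters
#' reproduces byte-identical files.
#' @param params a [synthetic_params()]
#' @param n number of samples
#' @param out_dir output directory (created)
#' @return the manifest, invisibly, as a list; `manifest$samples` is also
#'   summarised in a tibble at `manifest$table`
#' @export
generate_dataset <- function(params, n, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  samples <- vector("list", n)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  for (i in seq_len(n)) {
    rec <- generate_sample(params, index = i - 1L)
    nm <- sprintf("sample_%04d.png", i - 1L)
    ip <- file.path(out_dir, "images", nm)
    mp <- file.path(out_dir, "masks", nm)
    png::writePNG(rec$image, ip)
    png::writePNG(rec$mask, mp)
    written <- c(written, ip, mp)
    samples[[i]] <- c(list(file = nm,
                           split = if ((i - 1L) %% 2L == 0L) "train" else "test",
                           mask_pixels = sum(rec$mask)),
                      rec$meta)
  }
  manifest <- list(params = unclass(params), n = n,
                   split_rule = "even indices train, odd indices test",
                   samples = samples)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  manifest$table <- tibble::tibble(
    file = vapply(samples, `[[`, character(1), "file"),
    split = vapply(samples, `[[`, character(1), "split"),
    mask_pixels = vapply(samples, `[[`, numeric(1), "mask_pixels"),
    n_blobs = vapply(samples, function(s) length(s$blobs), numeric(1))
  )
  invisible(manifest)
}
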