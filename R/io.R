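# Small image IO helpers. PNG everywhere (lossless fixtures); JPEG inputs
# are read when the jpeg package is available.

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stop("reading JPEG requires the jpeg package; convert to PNG", call. = FALSE)
    }
    jpeg::readJPEG(path)
  } else {
    png::readPNG(path)
  }
  d <- dim(img)
  if (length(d) == 2L) {
    img <- array(rep(img, 3L), dim = c(d, 3L))
  } else if (d[3] >= 4L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

read_gray_png <- function(path) {
  img <- png::readPNG(path)
  d <- dim(img)
  if (length(d) == 3L) img <- img[, , 1]
  img
}

#' Read a binary mask PNG (foreground = 255, binarized at 128/255)
#' @param path PNG file
#' @return binary matrix `(H, W)` of 0/1
#' @export
read_mask_png <- function(path) {
  (read_gray_png(path) >= 128 / 255) * 1
}

#' Write a binary mask (or probability map) as an 8-bit grayscale PNG
#' @param mask matrix in `[0, 1]`
#' @param path output file
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(pmin(pmax(mask, 0), 1), path)
  invisible(path)
}

# bilinear / nearest rescale of a (H,W[,C]) image array
resize_image <- function(img, out_hw, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(img)
  chans <- if (length(d) == 3L) d[3] else 1L
  if (length(d) == 2L) dim(img) <- c(d, 1L)
  if (method == "bilinear") {
    x <- aperm(img, c(3, 1, 2))
    dim(x) <- c(chans, d[1], d[2], 1L)
    y <- .bilinear_fw(x, dim(x), as.integer(out_hw[1]), as.integer(out_hw[2]))
    out <- aperm(array(y, dim = dim(y)[1:3]), c(2, 3, 1))
  } else {
    ri <- pmin(d[1], pmax(1L, round((seq_len(out_hw[1]) - 0.5) * d[1] / out_hw[1] + 0.5)))
    ci <- pmin(d[2], pmax(1L, round((seq_len(out_hw[2]) - 0.5) * d[2] / out_hw[2] + 0.5)))
    out <- img[ri, ci, , drop = FALSE]
  }
  if (length(d) == 2L) dim(out) <- out_hw
  out
}
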