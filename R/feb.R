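# Feature-enhancing block (FEB): a multi-branch receptive-field block with
# progressively larger separable kernels and increasing dilation, applied
# independently to the three deepest encoder levels. Branch k (k >= 1) is
# 1x1 -> 1x(2k+1) -> (2k+1)x1 -> 3x3 with dilation rate[k]; branch 0 is a
# plain 1x1. Branches are concatenated, fused by a 3x3 conv, and summed with
# a 1x1 shortcut before the final ReLU.

#' FEB configuration
#'
#' @param in_channels channels of the incoming encoder level
#' @param out_channels channels of the enhanced map (shared by all three FEBs
#'   so the partial decoder can aggregate them)
#' @param dilation_rates strictly increasing dilation of the 3x3 conv ending
#'   each non-trivial branch; its length sets the number of such branches
#' @param norm `"bn"` (default) or `"none"` for batch-size-1 inference
#' @return an `feb_config` list
#' @export
feb_config <- function(in_channels, out_channels, dilation_rates = c(3L, 5L, 7L),
                       norm = c("bn", "none")) {
  norm <- match.arg(norm)
  if (any(diff(dilation_rates) <= 0)) {
    stop("`dilation_rates` must be strictly increasing", call. = FALSE)
  }
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 dilation_rates = as.integer(dilation_rates),
                 norm = norm),
            class = "feb_config")
}

build_feb <- function(ps, name, cfg) {
  cin <- cfg$in_channels; cout <- cfg$out_channels
  rates <- cfg$dilation_rates; norm <- cfg$norm
  nb <- length(rates)
  branches <- vector("list", nb + 1L)
  branches[[1]] <- list(conv_layer(ps, paste0(name, ".b0.conv0"), cin, cout,
                                   k = 1L, norm = norm, act = "relu"))
  for (k in seq_len(nb)) {
    kk <- 2L * k + 1L
    pfx <- sprintf("%s.b%d", name, k)
    branches[[k + 1L]] <- list(
      conv_layer(ps, paste0(pfx, ".conv0"), cin, cout, k = 1L, norm = norm, act = "relu"),
      conv_layer(ps, paste0(pfx, ".conv1"), cout, cout, k = c(1L, kk), norm = norm, act = "relu"),
      conv_layer(ps, paste0(pfx, ".conv2"), cout, cout, k = c(kk, 1L), norm = norm, act = "relu"),
      conv_layer(ps, paste0(pfx, ".conv3"), cout, cout, k = 3L,
                 dilation = rates[k], norm = norm, act = "relu")
    )
  }
  fuse <- conv_layer(ps, paste0(name, ".fuse"), (nb + 1L) * cout, cout,
                     k = 3L, norm = norm)
  shortcut <- conv_layer(ps, paste0(name, ".shortcut"), cin, cout,
                         k = 1L, norm = norm)
  forward <- function(x, training = FALSE) {
    outs <- lapply(branches, function(layers) {
      y <- x
      for (ly in layers) y <- ly(y, training)
      y
    })
    op_relu(op_add(fuse(op_concat_ch(outs), training), shortcut(x, training)))
  }
  structure(list(cfg = cfg, forward = forward, name = name), class = "mmnet_feb")
}

#' Run a feature-enhancing block on one feature map
#'
#' @param feb a built FEB (internal to a model, or from `build_feb`)
#' @param x array `(C_in, h, w)` or `(C_in, h, w, N)`
#' @param training batch-norm mode
#' @return array with `out_channels` channels and unchanged spatial size
#' @export
feb_forward <- function(feb, x, training = FALSE) {
  stopifnot(inherits(feb, "mmnet_feb"))
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (dim(x)[1] != feb$cfg$in_channels) {
    stop(sprintf("feature map has %d channels but the FEB expects %d",
                 dim(x)[1], feb$cfg$in_channels), call. = FALSE)
  }
  out <- feb$forward(new_tensor(x), training = training)$value
  if (length(d) == 3L) dim(out) <- dim(out)[1:3]
  out
}

#' Analytic receptive-field sizes of the FEB branches
#'
#' Bookkeeping over kernel sizes and dilations (stride is 1 everywhere inside
#' the block): a `(kh, kw)` conv with dilation `d` grows the receptive field
#' by `(kh-1)*d` rows and `(kw-1)*d` columns.
#' @param cfg an [feb_config()]
#' @return integer vector, one receptive-field side length per branch
#'   (square by symmetry of the paired separable kernels)
#' @export
feb_receptive_fields <- function(cfg) {
  stopifnot(inherits(cfg, "feb_config"))
  rates <- cfg$dilation_rates
  c(1L, vapply(seq_along(rates), function(k) {
    1L + 2L * k + 2L * rates[k]
  }, integer(1)))
}
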