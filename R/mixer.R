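# The feature-mixing module: the global feature map is patch-embedded into a
# token grid, passed through `depth` residual mixing blocks (depth-wise
# convolution mixes spatially, 1x1 convolution mixes across channels, layer
# normalization and GELU throughout, one residual connection around each
# half-block), then spatially averaged and squashed by a sigmoid into one
# weight per channel. That weight vector gates the global feature map
# multiplicatively — an attention-free, convolutional stand-in for
# channel attention.

#' Mixing-module configuration
#'
#' @param depth number of mixing blocks (model default 20)
#' @param dim embedding dimension of the token grid (default 64; the default
#'   model sets it equal to the global map's channels so the pooled vector
#'   gates that map directly)
#' @param kernel_size depth-wise kernel (default 28; with the default token
#'   grid of about 40x40 this mixes near-globally)
#' @param patch_size patch embedding kernel/stride (default 9)
#' @param operate_resolution `"input"` (upsample the global map to the network
#'   input size before patching; default) or `"stride8"` (patch the global map
#'   directly; the kernel is clamped to the token-grid side)
#' @param ln logical; keep layer normalization enabled (disabling is only
#'   useful for identity-path diagnostics)
#' @return a `mixer_config` list
#' @export
mixer_config <- function(depth = 20L, dim = 64L, kernel_size = 28L,
                         patch_size = 9L,
                         operate_resolution = c("input", "stride8"),
                         ln = TRUE) {
  operate_resolution <- match.arg(operate_resolution)
  stopifnot(depth >= 0L, dim >= 1L, kernel_size >= 1L, patch_size >= 1L)
  structure(list(depth = as.integer(depth), dim = as.integer(dim),
                 kernel_size = as.integer(kernel_size),
                 patch_size = as.integer(patch_size),
                 operate_resolution = operate_resolution, ln = ln),
            class = "mixer_config")
}

build_mixer <- function(ps, name, cg, cfg) {
  p <- cfg$patch_size
  embed_conv <- conv_layer(ps, paste0(name, ".embed"), cg, cfg$dim,
                           k = p, stride = p, pad = c(0L, 0L, 0L, 0L),
                           bias = TRUE)
  embed_ln <- if (cfg$ln) ln_layer(ps, paste0(name, ".embed"), cfg$dim)
  blocks <- lapply(seq_len(cfg$depth), function(l) {
    pfx <- sprintf("%s.block%d", name, l)
    list(
      dw = conv_layer(ps, paste0(pfx, ".dw"), cfg$dim, cfg$dim,
                      k = cfg$kernel_size, groups = cfg$dim, bias = TRUE),
      ln_a = ln_layer(ps, paste0(pfx, ".a"), cfg$dim),
      pw = conv_layer(ps, paste0(pfx, ".pw"), cfg$dim, cfg$dim,
                      k = 1L, bias = TRUE),
      ln_b = ln_layer(ps, paste0(pfx, ".b"), cfg$dim)
    )
  })
  structure(list(cfg = cfg, cg = cg, embed_conv = embed_conv,
                 embed_ln = embed_ln, blocks = blocks, name = name),
            class = "mmnet_mixer")
}

# clamp the depth-wise kernel to the token grid in stride8 mode
mixer_block_forward <- function(blk, z, training = FALSE) {
  z1 <- op_layer_or_id(blk$ln_a, op_add(op_gelu(blk$dw(z, training)), z))
  op_layer_or_id(blk$ln_b, op_add(op_gelu(blk$pw(z1, training)), z1))
}

op_layer_or_id <- function(layer, x) if (is.null(layer)) x else layer(x)

mixer_embed_tensor <- function(mixer, g, training = FALSE) {
  p <- mixer$cfg$patch_size
  d <- dim(g$value)
  pad_h <- (p - d[2] %% p) %% p
  pad_w <- (p - d[3] %% p) %% p
  if (pad_h > 0L || pad_w > 0L) {
    g <- op_pad_reflect(g, c(floor(pad_h / 2), ceiling(pad_h / 2),
                             floor(pad_w / 2), ceiling(pad_w / 2)))
  }
  z <- op_gelu(mixer$embed_conv(g, training))
  op_layer_or_id(mixer$embed_ln, z)
}

mixer_gate_tensor <- function(mixer, g_map, input_hw, training = FALSE) {
  g_op <- if (mixer$cfg$operate_resolution == "input") {
    op_upsample_bilinear(g_map, input_hw)
  } else g_map
  z <- mixer_embed_tensor(mixer, g_op, training)
  for (blk in mixer$blocks) z <- mixer_block_forward(blk, z, training)
  op_sigmoid(op_gap(z))
}

#' Patch-embed a global feature map into a token grid
#'
#' The map is reflect-padded so both spatial sides divide by the patch size,
#' then embedded by a `p x p` convolution with stride `p`, GELU, and layer
#' normalization over channels.
#' @param mixer a built mixing module
#' @param G array `(C_g, h, w[, N])` (already at the operating resolution)
#' @param training unused placeholder for layer symmetry
#' @return token array `(dim, ceil(h/p), ceil(w/p)[, N])`
#' @export
patch_embed <- function(mixer, G, training = FALSE) {
  stopifnot(inherits(mixer, "mmnet_mixer"))
  squeeze <- length(dim(G)) == 3L
  if (squeeze) dim(G) <- c(dim(G), 1L)
  out <- mixer_embed_tensor(mixer, new_tensor(G), training)$value
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

#' Apply one residual mixing block to a token grid
#'
#' Computes `z_a = LN(GELU(DepthwiseConv(z)) + z)` followed by
#' `z_b = LN(GELU(PointwiseConv(z_a)) + z_a)`; the depth-wise convolution is
#' "same"-padded so the grid size never changes.
#' @param mixer a built mixing module
#' @param z token array `(dim, ht, wt[, N])`
#' @param block which of the `depth` blocks to apply (weights differ)
#' @param training unused placeholder
#' @return token array of identical shape
#' @export
mix_block <- function(mixer, z, block = 1L, training = FALSE) {
  stopifnot(inherits(mixer, "mmnet_mixer"), block >= 1L,
            block <= length(mixer$blocks))
  squeeze <- length(dim(z)) == 3L
  if (squeeze) dim(z) <- c(dim(z), 1L)
  out <- mixer_block_forward(mixer$blocks[[block]], new_tensor(z), training)$value
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

#' Pool a token grid into per-channel sigmoid gate weights
#'
#' Global average pooling over space followed by a sigmoid; every entry is
#' strictly inside (0, 1).
#' @param z_final token array `(C, ht, wt[, N])`
#' @return matrix `(C, N)` of gate weights
#' @export
channel_gate <- function(z_final) {
  squeeze <- length(dim(z_final)) == 3L
  if (squeeze) dim(z_final) <- c(dim(z_final), 1L)
  g <- op_sigmoid(op_gap(new_tensor(z_final)))$value
  g
}

#' Gate a global feature map channel-wise
#'
#' @param G array `(C, h, w[, N])`
#' @param gate vector of length `C`, or matrix `(C, N)`
#' @return array of `G`'s shape with channel `c` scaled by `gate[c]`
#' @export
apply_gate <- function(G, gate) {
  squeeze <- length(dim(G)) == 3L
  if (squeeze) dim(G) <- c(dim(G), 1L)
  d <- dim(G)
  gate <- as.matrix(gate)
  if (ncol(gate) == 1L && d[4] > 1L) gate <- gate[, rep(1L, d[4]), drop = FALSE]
  if (nrow(gate) != d[1]) {
    stop(sprintf("gate has length %d but the map has %d channels",
                 nrow(gate), d[1]), call. = FALSE)
  }
  out <- op_mul_channel(new_tensor(G), new_tensor(gate))$value
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

#' Collapse a gated map to a mask probability map
#'
#' A 1x1 convolution to one channel, bilinear upsampling to `out_size`, and a
#' sigmoid. (The reduction from the multi-channel gated map to a 1-channel
#' mask is plumbing this package defines; the gating itself ends at the
#' channel-weighted map.)
#' @param head the model's mask head (see [build_mmnet()], `$head`)
#' @param gated array `(C_g, h, w[, N])`
#' @param out_size `(H, W)` of the returned probability map
#' @return array `(H, W[, N])` of probabilities in `[0, 1]`
#' @export
mask_head <- function(head, gated, out_size) {
  squeeze <- length(dim(gated)) == 3L
  if (squeeze) dim(gated) <- c(dim(gated), 1L)
  out <- mask_head_tensor(head, new_tensor(gated), out_size)$value
  out <- array(out, dim = c(out_size[1], out_size[2], dim(out)[4]))
  if (squeeze) dim(out) <- out_size
  out
}

mask_head_tensor <- function(head, gated, out_size, training = FALSE) {
  op_sigmoid(op_upsample_bilinear(head(gated, training), out_size))
}
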