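# Pyramid feature encoders behind a uniform contract: every backbone maps an
# RGB batch to four feature maps at strides 4/8/16/32. Two encoders are
# provided: `pvt_v2_b2`, the Pyramid Vision Transformer v2 (b2 capacity:
# overlapping patch embeds, spatial-reduction attention, depthwise-conv FFN),
# and `tiny_test`, a small strided convolutional encoder for CPU work.
#
# Image batches are passed as (H, W, 3) or (H, W, 3, N) arrays in [0, 1]
# (the layout png::readPNG produces); feature maps come back as
# (C, H/stride, W/stride, N) arrays.

PYRAMID_STRIDES <- c(4L, 8L, 16L, 32L)

#' Describe a pyramid backbone
#'
#' @param name `"pvt_v2_b2"` or `"tiny_test"`
#' @param out_channels integer vector of length 4, channels of the four
#'   pyramid levels (defaults: PVTv2-b2 `c(64,128,320,512)`, tiny
#'   `c(8,16,32,64)`)
#' @param pretrained logical; only permitted for `pvt_v2_b2`, and then a
#'   checkpoint file must be supplied to [build_backbone()]
#' @return a `backbone_spec` list with fields `name`, `out_channels`,
#'   `strides` (always `c(4,8,16,32)`), `pretrained`
#' @export
backbone_spec <- function(name = c("tiny_test", "pvt_v2_b2"),
                          out_channels = NULL, pretrained = FALSE) {
  name <- match.arg(name)
  if (is.null(out_channels)) {
    out_channels <- if (name == "pvt_v2_b2") c(64L, 128L, 320L, 512L)
                    else c(8L, 16L, 32L, 64L)
  }
  out_channels <- as.integer(out_channels)
  if (length(out_channels) != 4L || any(out_channels <= 0L)) {
    stop("`out_channels` must be 4 positive integers", call. = FALSE)
  }
  if (pretrained && name != "pvt_v2_b2") {
    stop("`pretrained` is only available for the pvt_v2_b2 backbone", call. = FALSE)
  }
  structure(list(name = name, out_channels = out_channels,
                 strides = PYRAMID_STRIDES, pretrained = pretrained),
            class = "backbone_spec")
}

#' Build a backbone (weights + spec) from a spec
#'
#' @param spec a [backbone_spec()]
#' @param seed integer seed for weight initialization
#' @param checkpoint optional path to an `.rds` of parameter arrays (required
#'   when `spec$pretrained` is `TRUE`)
#' @return an `mmnet_backbone`: list with `spec`, `ps` (parameters) and
#'   `forward(x, training)`
#' @export
build_backbone <- function(spec, seed = 0L, checkpoint = NULL) {
  stopifnot(inherits(spec, "backbone_spec"))
  set.seed(as.integer(seed))
  ps <- new_param_set()
  fwd <- switch(spec$name,
    tiny_test = build_tiny_encoder(ps, spec$out_channels),
    pvt_v2_b2 = build_pvt_v2(ps, spec$out_channels),
    stop("unknown backbone name: ", spec$name, call. = FALSE)
  )
  bb <- structure(list(spec = spec, ps = ps, forward = fwd),
                  class = "mmnet_backbone")
  if (spec$pretrained) {
    if (is.null(checkpoint)) {
      stop("pretrained pvt_v2_b2 requires a `checkpoint` file of weights; ",
           "none was supplied", call. = FALSE)
    }
    vals <- readRDS(checkpoint)
    load_param_values(ps, vals)
  }
  bb
}

#' Construct the tiny seeded test backbone
#'
#' A 4-stage strided convolutional encoder honouring the pyramid contract;
#' initialization is fully determined by `seed`.
#' @param seed integer seed
#' @param out_channels 4 channel counts, all at least 4
#' @return an `mmnet_backbone`
#' @export
make_tiny_backbone <- function(seed = 0L, out_channels = c(8L, 16L, 32L, 64L)) {
  if (any(out_channels < 4L)) {
    stop("tiny backbone `out_channels` must all be >= 4", call. = FALSE)
  }
  build_backbone(backbone_spec("tiny_test", out_channels), seed = seed)
}

build_tiny_encoder <- function(ps, ch) {
  s1a <- conv_layer(ps, "backbone.s1a", 3L, ch[1], k = 3L, stride = 2L,
                    norm = "bn", act = "relu")
  s1b <- conv_layer(ps, "backbone.s1b", ch[1], ch[1], k = 3L, stride = 2L,
                    norm = "bn", act = "relu")
  s2 <- conv_layer(ps, "backbone.s2", ch[1], ch[2], k = 3L, stride = 2L,
                   norm = "bn", act = "relu")
  s3 <- conv_layer(ps, "backbone.s3", ch[2], ch[3], k = 3L, stride = 2L,
                   norm = "bn", act = "relu")
  s4 <- conv_layer(ps, "backbone.s4", ch[3], ch[4], k = 3L, stride = 2L,
                   norm = "bn", act = "relu")
  function(x, training = FALSE) {
    f1 <- s1b(s1a(x, training), training)
    f2 <- s2(f1, training)
    f3 <- s3(f2, training)
    f4 <- s4(f3, training)
    list(f1, f2, f3, f4)
  }
}

# --- PVTv2-b2 ---------------------------------------------------------------

build_pvt_v2 <- function(ps, ch) {
  depths <- c(3L, 4L, 6L, 3L)
  heads <- c(1L, 2L, 5L, 8L)
  mlp_ratios <- c(8L, 8L, 4L, 4L)
  sr_ratios <- c(8L, 4L, 2L, 1L)
  stages <- vector("list", 4L)
  for (s in 1:4) {
    pfx <- sprintf("backbone.stage%d", s)
    cin <- if (s == 1) 3L else ch[s - 1]
    k <- if (s == 1) 7L else 3L
    st <- if (s == 1) 4L else 2L
    embed <- conv_layer(ps, paste0(pfx, ".embed"), cin, ch[s], k = k, stride = st,
                        pad = rep((k - 1L) %/% 2L, 4L), bias = TRUE)
    embed_ln <- ln_tokens_layer(ps, paste0(pfx, ".embed"), ch[s])
    blocks <- lapply(seq_len(depths[s]), function(b) {
      pvt_block(ps, sprintf("%s.block%d", pfx, b), ch[s], heads[s],
                mlp_ratios[s], sr_ratios[s])
    })
    out_ln <- ln_tokens_layer(ps, paste0(pfx, ".out"), ch[s])
    stages[[s]] <- list(embed = embed, embed_ln = embed_ln,
                        blocks = blocks, out_ln = out_ln)
  }
  function(x, training = FALSE) {
    maps <- vector("list", 4L)
    cur <- x
    for (s in 1:4) {
      st <- stages[[s]]
      m <- st$embed(cur, training)
      d <- dim(m$value)
      H <- d[2]; W <- d[3]
      z <- st$embed_ln(op_tokens(m))
      for (blk in st$blocks) z <- blk(z, H, W, training)
      z <- st$out_ln(z)
      cur <- op_chw(z, H, W)
      maps[[s]] <- cur
    }
    maps
  }
}

pvt_block <- function(ps, pfx, C, heads, mlp_ratio, sr) {
  ln1 <- ln_tokens_layer(ps, paste0(pfx, ".ln1"), C)
  q_lin <- linear_layer(ps, paste0(pfx, ".q"), C, C)
  k_lin <- linear_layer(ps, paste0(pfx, ".k"), C, C)
  v_lin <- linear_layer(ps, paste0(pfx, ".v"), C, C)
  proj <- linear_layer(ps, paste0(pfx, ".proj"), C, C)
  sr_conv <- if (sr > 1L) {
    conv_layer(ps, paste0(pfx, ".sr"), C, C, k = sr, stride = sr,
               pad = c(0L, 0L, 0L, 0L), bias = TRUE)
  }
  sr_ln <- if (sr > 1L) ln_tokens_layer(ps, paste0(pfx, ".sr"), C)
  ln2 <- ln_tokens_layer(ps, paste0(pfx, ".ln2"), C)
  hidden <- C * mlp_ratio
  fc1 <- linear_layer(ps, paste0(pfx, ".fc1"), C, hidden)
  dw <- conv_layer(ps, paste0(pfx, ".dw"), hidden, hidden, k = 3L,
                   groups = hidden, bias = TRUE)
  fc2 <- linear_layer(ps, paste0(pfx, ".fc2"), hidden, C)
  Dh <- C %/% heads
  scale <- Dh^(-0.5)
  function(z, H, W, training = FALSE) {
    d <- dim(z$value)
    Tq <- d[1]; N <- d[3]
    zn <- ln1(z)
    q <- q_lin(zn)
    kv_src <- if (sr > 1L) {
      sr_ln(op_tokens(sr_conv(op_chw(zn, H, W), training)))
    } else zn
    Tk <- dim(kv_src$value)[1]
    k <- k_lin(kv_src)
    v <- v_lin(kv_src)
    qh <- op_reshape(q, c(Tq, Dh, heads * N))
    kh <- op_reshape(k, c(Tk, Dh, heads * N))
    vh <- op_reshape(v, c(Tk, Dh, heads * N))
    attn <- op_softmax2(op_scale(op_bmm(qh, op_transpose12(kh)), scale))
    out <- op_reshape(op_bmm(attn, vh), c(Tq, C, N))
    z <- op_add(z, proj(out))
    zn <- ln2(z)
    h <- fc1(zn)
    h <- op_tokens(dw(op_chw(h, H, W), training))
    h <- fc2(op_gelu_tokens(h))
    op_add(z, h)
  }
}

op_gelu_tokens <- op_gelu   # GELU is shape-agnostic

load_param_values <- function(ps, vals) {
  for (nm in names(vals)) {
    if (is.null(ps$params[[nm]])) stop("checkpoint has unknown parameter: ", nm)
    stopifnot(length(ps$params[[nm]]$value) == length(vals[[nm]]))
    d <- dim(ps$params[[nm]]$value)
    v <- as.vector(vals[[nm]])
    if (!is.null(d)) dim(v) <- d
    ps$params[[nm]]$value <- v
  }
  invisible(ps)
}

# --- pyramid extraction -----------------------------------------------------

# Convert (H,W,3[,N]) image batch in [0,1] to internal (3,H,W,N)
image_batch_to_chw <- function(images) {
  d <- dim(images)
  if (length(d) == 3L) dim(images) <- c(d, 1L)
  aperm(images, c(3, 1, 2, 4))
}

chw_to_image_batch <- function(x) aperm(x, c(2, 3, 1, 4))

#' Extract the four-level feature pyramid from an image batch
#'
#' @param images array `(H, W, 3)` or `(H, W, 3, N)` in `[0, 1]` (already
#'   normalized by the caller if desired)
#' @param backbone an `mmnet_backbone` from [build_backbone()] /
#'   [make_tiny_backbone()]
#' @param training logical, batch-norm mode for the tiny encoder
#' @return list of 4 arrays `(C_m, H/stride_m, W/stride_m, N)` for strides
#'   4, 8, 16, 32
#' @export
extract_pyramid <- function(images, backbone, training = FALSE) {
  stopifnot(inherits(backbone, "mmnet_backbone"))
  d <- dim(images)
  H <- d[1]; W <- d[2]
  if (H %% 32L != 0L) {
    stop(sprintf("image height %d is not divisible by 32 (pad first)", H), call. = FALSE)
  }
  if (W %% 32L != 0L) {
    stop(sprintf("image width %d is not divisible by 32 (pad first)", W), call. = FALSE)
  }
  x <- new_tensor(image_batch_to_chw(images))
  maps <- backbone$forward(x, training = training)
  lapply(maps, function(m) m$value)
}
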