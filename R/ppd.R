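# Parallel partial decoder (PPD): aggregates the three enhanced high-level
# maps (strides 8/16/32) into one global feature map at stride 8, discarding
# level-1 features. The aggregation is the cascaded partial-decoder topology:
# deeper context is upsampled, refined by 3x3 convs and multiplied into
# shallower maps, then progressively concatenated and fused; the fusion convs
# carry a configurable dilation (default 2).

build_ppd <- function(ps, name, C, cg, dilation = 2L) {
  cu <- lapply(1:4, function(i) {
    conv_layer(ps, sprintf("%s.up%d", name, i), C, C, k = 3L, norm = "bn", act = "relu")
  })
  cu[[5]] <- conv_layer(ps, paste0(name, ".up5"), 2L * C, 2L * C, k = 3L,
                        norm = "bn", act = "relu")
  cat2 <- conv_layer(ps, paste0(name, ".cat2"), 2L * C, 2L * C, k = 3L,
                     dilation = dilation, norm = "bn", act = "relu")
  cat3 <- conv_layer(ps, paste0(name, ".cat3"), 3L * C, 3L * C, k = 3L,
                     dilation = dilation, norm = "bn", act = "relu")
  conv4 <- conv_layer(ps, paste0(name, ".fuse"), 3L * C, 3L * C, k = 3L,
                      dilation = dilation, norm = "bn", act = "relu")
  conv5 <- conv_layer(ps, paste0(name, ".out"), 3L * C, cg, k = 1L, bias = TRUE)
  forward <- function(r2, r3, r4, training = FALSE) {
    s2 <- dim(r2$value)[2:3]; s3 <- dim(r3$value)[2:3]
    x1 <- r4; x2 <- r3; x3 <- r2
    x2_1 <- op_mul(cu[[1]](op_upsample_bilinear(x1, s3), training), x2)
    x3_1 <- op_mul(op_mul(cu[[2]](op_upsample_bilinear(x1, s2), training),
                          cu[[3]](op_upsample_bilinear(x2, s2), training)), x3)
    x2_2 <- cat2(op_concat_ch(list(
      x2_1, cu[[4]](op_upsample_bilinear(x1, s3), training))), training)
    x3_2 <- cat3(op_concat_ch(list(
      x3_1, cu[[5]](op_upsample_bilinear(x2_2, s2), training))), training)
    conv5(conv4(x3_2, training), training)
  }
  structure(list(C = C, cg = cg, dilation = dilation, forward = forward,
                 name = name), class = "mmnet_ppd")
}

#' Aggregate enhanced pyramid levels into the global feature map
#'
#' @param ppd a built partial decoder
#' @param R2,R3,R4 arrays `(C, h, w[, N])` at strides 8/16/32: each map half
#'   the spatial size of the previous, all with the same channel count
#' @param training batch-norm mode
#' @return array `(C_g, h2, w2[, N])` at `R2`'s resolution
#' @export
ppd_aggregate <- function(ppd, R2, R3, R4, training = FALSE) {
  stopifnot(inherits(ppd, "mmnet_ppd"))
  maps <- list(R2 = R2, R3 = R3, R4 = R4)
  squeeze <- length(dim(R2)) == 3L
  maps <- lapply(maps, function(m) {
    d <- dim(m)
    if (length(d) == 3L) dim(m) <- c(d, 1L)
    m
  })
  ch <- vapply(maps, function(m) dim(m)[1], integer(1))
  if (length(unique(ch)) != 1L) {
    stop("R2/R3/R4 must share a channel count; got ",
         paste(ch, collapse = "/"), call. = FALSE)
  }
  for (k in 1:2) {
    a <- dim(maps[[k]])[2:3]; b <- dim(maps[[k + 1]])[2:3]
    if (!all(a == 2L * b)) {
      stop(sprintf("spatial sizes must halve down the chain; level %d is %dx%d, level %d is %dx%d",
                   k + 1L, a[1], a[2], k + 2L, b[1], b[2]), call. = FALSE)
    }
  }
  out <- ppd$forward(new_tensor(maps$R2), new_tensor(maps$R3),
                     new_tensor(maps$R4), training = training)$value
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}
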