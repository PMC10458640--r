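# End-to-end model assembly: pyramid encoder -> feature enhancers on the
# three deepest levels -> partial decoder -> mixing-module channel gate ->
# mask head. Every block can be ablated; a disabled block is replaced by a
# parameter-free stand-in so that any ablation combination still builds and
# runs.

#' Build an MMNet model from a configuration
#'
#' @param config an [mmnet_config()]
#' @param seed integer; fixes every weight initialization
#' @return an `mmnet_model` list: `config`, `ps` (parameter set), `backbone`
#'   (an `mmnet_backbone`), `febs`, `ppd`, `mixer`, `head`, and
#'   `forward(images, training, normalize)`
#' @export
build_mmnet <- function(config = mmnet_config(), seed = config$seed) {
  stopifnot(inherits(config, "mmnet_config"))
  set.seed(as.integer(seed))
  ps <- new_param_set()
  bspec <- backbone_spec(config$backbone$name,
                         out_channels = config$backbone$out_channels,
                         pretrained = isTRUE(config$backbone$pretrained))
  bb_fwd <- switch(bspec$name,
    tiny_test = build_tiny_encoder(ps, bspec$out_channels),
    pvt_v2_b2 = build_pvt_v2(ps, bspec$out_channels)
  )
  backbone <- structure(list(spec = bspec, ps = ps, forward = bb_fwd),
                        class = "mmnet_backbone")
  if (bspec$pretrained) {
    if (is.null(config$backbone$checkpoint)) {
      stop("pretrained pvt_v2_b2 requires `backbone$checkpoint`", call. = FALSE)
    }
    load_param_values(ps, readRDS(config$backbone$checkpoint))
  }

  cg <- config$ppd$out_channels
  ab <- config$ablation
  febs <- vector("list", 3L)
  for (m in 1:3) {
    if (isTRUE(ab[[paste0("feb", m)]])) {
      cfg_m <- feb_config(bspec$out_channels[m + 1L], config$feb$out_channels,
                          config$feb$dilation_rates, config$feb$norm)
      febs[[m]] <- build_feb(ps, paste0("feb", m), cfg_m)
    }
  }
  ppd <- if (isTRUE(ab$ppd)) {
    build_ppd(ps, "ppd", config$feb$out_channels, cg, config$ppd$dilation)
  }
  mixer <- if (isTRUE(ab$mixer)) {
    mcfg <- do.call(mixer_config, config$mixer)
    if (mcfg$dim != cg) {
      stop(sprintf("mixer dim (%d) must equal the global map channels (%d) ",
                   mcfg$dim, cg),
           "so the pooled gate applies directly; set ppd$out_channels = mixer$dim",
           call. = FALSE)
    }
    if (mcfg$operate_resolution == "stride8") {
      grid <- ceiling((config$image_size %/% 8L) / mcfg$patch_size)
      mcfg$kernel_size <- min(mcfg$kernel_size, grid)
    }
    build_mixer(ps, "mixer", cg, mcfg)
  }
  head <- conv_layer(ps, "head", cg, 1L, k = 1L, pad = c(0L, 0L, 0L, 0L),
                     bias = TRUE)

  forward <- function(images, training = FALSE, normalize = TRUE,
                      detail = FALSE) {
    d <- dim(images)
    if (length(d) == 3L) dim(images) <- c(d, 1L)
    H <- dim(images)[1]; W <- dim(images)[2]
    if (H %% 32L || W %% 32L) {
      stop(sprintf("input %dx%d is not divisible by 32", H, W), call. = FALSE)
    }
    if (normalize) images <- normalize_images(images, config$normalize)
    x <- new_tensor(image_batch_to_chw(images))
    pyr <- bb_fwd(x, training = training)
    enhanced <- vector("list", 3L)
    for (m in 1:3) {
      enhanced[[m]] <- if (!is.null(febs[[m]])) {
        febs[[m]]$forward(pyr[[m + 1L]], training = training)
      } else {
        op_channel_resample(pyr[[m + 1L]], cg)
      }
    }
    g_map <- if (!is.null(ppd)) {
      ppd$forward(enhanced[[1]], enhanced[[2]], enhanced[[3]],
                  training = training)
    } else {
      s2 <- dim(enhanced[[1]]$value)[2:3]
      op_add(enhanced[[1]],
             op_add(op_upsample_bilinear(enhanced[[2]], s2),
                    op_upsample_bilinear(enhanced[[3]], s2)))
    }
    gate <- if (!is.null(mixer)) {
      mixer_gate_tensor(mixer, g_map, c(H, W), training = training)
    }
    gated <- if (!is.null(gate)) op_mul_channel(g_map, gate) else g_map
    prob <- mask_head_tensor(head, gated, c(H, W), training = training)
    if (detail) list(prob = prob, gate = gate, g_map = g_map, pyramid = pyr)
    else prob
  }

  structure(list(config = config, ps = ps, backbone = backbone, febs = febs,
                 ppd = ppd, mixer = mixer, head = head, forward = forward),
            class = "mmnet_model")
}

normalize_images <- function(images, nz) {
  d <- dim(images)
  for (c in 1:3) {
    images[, , c, ] <- (images[, , c, ] - nz$mean[c]) / nz$sd[c]
  }
  images
}

#' Forward pass: images to mask probabilities
#'
#' @param model an `mmnet_model`
#' @param images array `(H, W, 3)` or `(H, W, 3, N)` in `[0, 1]`; sides must
#'   divide by 32
#' @param training batch-norm mode (use `TRUE` only inside the train loop)
#' @param normalize apply the configured channel normalization first
#' @return array `(H, W)` / `(H, W, N)` of probabilities in `[0, 1]`
#' @export
mmnet_forward <- function(model, images, training = FALSE, normalize = TRUE) {
  stopifnot(inherits(model, "mmnet_model"))
  squeeze <- length(dim(images)) == 3L
  t <- model$forward(images, training = training, normalize = normalize)
  v <- t$value
  out <- array(v, dim = dim(v)[c(2, 3, 4)])
  if (squeeze) dim(out) <- dim(out)[1:2]
  out
}

#' @export
print.mmnet_model <- function(x, ...) {
  ab <- x$config$ablation
  on <- names(ab)[vapply(ab, isTRUE, logical(1))]
  cat(sprintf("<mmnet_model> backbone %s, %d parameters\n",
              x$backbone$spec$name, n_parameters(x)))
  cat("  active blocks:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Check that the mixing module normalizes with layer norm only
#'
#' Introspects the built model's parameter names: the mixing module must
#' contain layer-norm scale/shift parameters and no batch-norm state.
#' @param model an `mmnet_model`
#' @return TRUE (invisibly) or an error
#' @export
assert_mixer_layernorm <- function(model) {
  nm <- names(model$ps$params)
  mix <- nm[startsWith(nm, "mixer.")]
  if (!length(mix)) stop("model has no mixing module", call. = FALSE)
  if (!any(grepl("\\.ln\\.", mix))) {
    stop("mixing module has no layer-norm parameters", call. = FALSE)
  }
  if (any(grepl("\\.bn\\.", mix)) ||
      any(startsWith(names(model$ps$buffers), "mixer."))) {
    stop("mixing module contains batch-norm state", call. = FALSE)
  }
  invisible(TRUE)
}
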