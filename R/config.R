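# Model/training configuration. `mmnet_config()` carries every architecture
# and recipe hyperparameter at its published default; presets scale it down
# for CPU work; YAML round-trip for file-driven runs.

#' Default MMNet configuration
#'
#' All fields can be overridden through `...` (nested lists are merged
#' recursively). Defaults follow the published recipe: 352x352 inputs,
#' mixing module with depth 20 / dim 64 / kernel 28 / patch 9, Adam at
#' 1e-4 with polynomial decay, 60 epochs, batch 16, multi-scale training at
#' factors {0.75, 1, 1.25}, rotation up to 90 degrees plus flips and
#' rescaling.
#'
#' @param ... named overrides, e.g. `mixer = list(depth = 2)`
#' @return an `mmnet_config` nested list
#' @export
mmnet_config <- function(...) {
  base <- list(
    image_size = 352L,
    normalize = list(mean = c(0.485, 0.456, 0.406),
                     sd = c(0.229, 0.224, 0.225)),
    backbone = list(name = "pvt_v2_b2", out_channels = NULL,
                    pretrained = FALSE, checkpoint = NULL),
    feb = list(out_channels = 64L, dilation_rates = c(3L, 5L, 7L), norm = "bn"),
    ppd = list(out_channels = 64L, dilation = 2L),
    mixer = list(depth = 20L, dim = 64L, kernel_size = 28L, patch_size = 9L,
                 operate_resolution = "input"),
    ablation = list(feb1 = TRUE, feb2 = TRUE, feb3 = TRUE,
                    ppd = TRUE, mixer = TRUE),
    loss = list(reduction = "mean", weighted = FALSE),
    train = list(batch_size = 16L, epochs = 60L, base_lr = 1e-4,
                 lr_decay = list(kind = "poly", power = 0.9, factor = 0.1),
                 multiscale_factors = c(0.75, 1, 1.25),
                 augment = list(enabled = TRUE, rotate_max_deg = 90,
                                hflip = TRUE, vflip = TRUE,
                                rescale = c(0.8, 1.2)),
                 max_iterations = NULL,
                 val_every = 1L),
    seed = 1L
  )
  cfg <- merge_config(base, list(...))
  structure(cfg, class = "mmnet_config")
}

merge_config <- function(base, over) {
  for (i in seq_along(over)) {   # by position: duplicated names apply in order
    nm <- names(over)[i]
    if (is.list(over[[i]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[i]])
    } else {
      base[[nm]] <- over[[i]]
    }
  }
  base
}

#' Small CPU configuration (96x96 inputs, tiny backbone)
#'
#' The preset used by the package's smoke experiments: tiny seeded backbone,
#' 16-channel global map, mixing module with depth 2 / dim 16 / kernel 7 /
#' patch 4, full-batch Adam at 3e-3 with augmentation off.
#' @param ... further overrides
#' @return an `mmnet_config`
#' @export
mmnet_tiny_config <- function(...) {
  mmnet_config(
    image_size = 96L,
    backbone = list(name = "tiny_test"),
    feb = list(out_channels = 16L),
    ppd = list(out_channels = 16L),
    mixer = list(depth = 2L, dim = 16L, kernel_size = 7L, patch_size = 4L),
    train = list(batch_size = 8L, base_lr = 3e-3,
                 multiscale_factors = 1,
                 augment = list(enabled = FALSE)),
    ...
  )
}

#' Ablation-lattice configurations
#'
#' The six cumulative rows of the block-ablation study: backbone alone, then
#' adding the feature enhancers one by one, the partial decoder, and the
#' mixing module. When a block is off, a parameter-free stand-in keeps the
#' graph runnable (channel resampling for an absent FEB, upsample-and-sum
#' fusion for an absent PPD, a unit gate for an absent mixer), so consecutive
#' rows differ by exactly the added block's parameters.
#'
#' @param base an `mmnet_config` to toggle (default [mmnet_tiny_config()])
#' @return named list of six `mmnet_config`s, in lattice order
#' @export
ablation_lattice <- function(base = mmnet_tiny_config()) {
  rows <- list(
    backbone = list(feb1 = FALSE, feb2 = FALSE, feb3 = FALSE, ppd = FALSE, mixer = FALSE),
    feb1     = list(feb1 = TRUE,  feb2 = FALSE, feb3 = FALSE, ppd = FALSE, mixer = FALSE),
    feb2     = list(feb1 = TRUE,  feb2 = TRUE,  feb3 = FALSE, ppd = FALSE, mixer = FALSE),
    feb3     = list(feb1 = TRUE,  feb2 = TRUE,  feb3 = TRUE,  ppd = FALSE, mixer = FALSE),
    ppd      = list(feb1 = TRUE,  feb2 = TRUE,  feb3 = TRUE,  ppd = TRUE,  mixer = FALSE),
    full     = list(feb1 = TRUE,  feb2 = TRUE,  feb3 = TRUE,  ppd = TRUE,  mixer = TRUE)
  )
  lapply(rows, function(ab) {
    cfg <- base
    cfg$ablation <- ab
    cfg
  })
}

#' Read / write a configuration as YAML
#' @param path file path
#' @return an `mmnet_config`
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(mmnet_config, cfg)
}

#' @rdname read_config
#' @param config an `mmnet_config`
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
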