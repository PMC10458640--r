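# broom-style accessors and ggplot2 autoplot methods for the package's
# tabular result objects.

#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_boxplot labs
#'   facet_wrap theme_minimal
NULL

#' Tidy an evaluation: one row per image and metric
#' @param x an `mmnet_eval`
#' @param ... unused
#' @return long tibble `(image, metric, value)`
#' @export
tidy.mmnet_eval <- function(x, ...) {
  tidyr::pivot_longer(x$per_image, -"image",
                      names_to = "metric", values_to = "value")
}

#' One-row summary of an evaluation (the six aggregate metrics)
#' @param x an `mmnet_eval`
#' @param ... unused
#' @export
glance.mmnet_eval <- function(x, ...) {
  dplyr::mutate(x$aggregate, n_images = x$n_images, .before = 1)
}

#' Per-iteration training log
#' @param x an `mmnet_fit`
#' @param ... unused
#' @export
tidy.mmnet_fit <- function(x, ...) x$log

#' One-row training summary
#' @param x an `mmnet_fit`
#' @param ... unused
#' @export
glance.mmnet_fit <- function(x, ...) {
  ep <- dplyr::filter(x$log, .data$phase == "epoch")
  tibble::tibble(
    iterations = max(x$log$iteration),
    epochs = nrow(ep),
    final_loss = ep$loss[nrow(ep)],
    final_train_dice = ep$train_dice[nrow(ep)],
    best_val_dice = x$best$dice,
    best_epoch = x$best$epoch,
    parameters = n_parameters(x$model)
  )
}

#' @export
autoplot.mmnet_fit <- function(object, ...) {
  steps <- dplyr::filter(object$log, .data$phase == "train_step")
  ggplot(steps, aes(x = .data$iteration, y = .data$loss)) +
    geom_line(colour = "steelblue") +
    labs(x = "iteration", y = "total loss (BCE + IoU)",
         title = "training loss") +
    theme_minimal()
}

#' @export
autoplot.mmnet_eval <- function(object, ...) {
  ggplot(tidy.mmnet_eval(object),
         aes(x = .data$metric, y = .data$value)) +
    geom_boxplot(fill = "grey85") +
    labs(x = NULL, y = "value", title = "per-image evaluation metrics") +
    theme_minimal()
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
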