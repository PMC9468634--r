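# broom-style accessors and ggplot2 autoplot methods for the fitted objects.

#' @method tidy cssl_pretrain
#' @export
tidy.cssl_pretrain <- function(x, ...) x$history

#' @method glance cssl_pretrain
#' @export
glance.cssl_pretrain <- function(x, ...) {
  tibble::tibble(method = x$method, epochs = nrow(x$history),
                 first_loss = x$history$mean_loss[1],
                 final_loss = utils::tail(x$history$mean_loss, 1),
                 provenance = x$provenance)
}

#' @method tidy cssl_classifier
#' @export
tidy.cssl_classifier <- function(x, ...) x$history

#' @method glance cssl_classifier
#' @export
glance.cssl_classifier <- function(x, ...) {
  tibble::tibble(provenance = x$provenance, method = x$method,
                 epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_acc = if (x$best_epoch > 0) {
                   x$history$val_acc[x$best_epoch]
                 } else NA_real_)
}

#' @method tidy cssl_grid
#' @export
tidy.cssl_grid <- function(x, ...) x$runs

#' @method glance cssl_grid
#' @export
glance.cssl_grid <- function(x, ...) {
  dplyr::select(x$cells, -"accuracies")
}

#' @export
print.cssl_pretrain <- function(x, ...) {
  cat(sprintf("<cssl_pretrain> %s, %d epochs, loss %.4f -> %.4f\n",
              x$method, nrow(x$history), x$history$mean_loss[1],
              utils::tail(x$history$mean_loss, 1)))
  invisible(x)
}

#' @export
print.cssl_classifier <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cssl_classifier> init=%s, best epoch %d/%d, val acc %.1f%%\n",
              x$provenance, g$best_epoch, g$epochs,
              g$best_val_acc %||% NA_real_))
  invisible(x)
}

#' @export
print.cssl_grid <- function(x, ...) {
  cat("<cssl_grid>\n")
  print(glance(x))
  invisible(x)
}

#' Summarize a grid in the accuracy-table layout
#'
#' Mean accuracy with standard deviation per (label fraction, method) cell,
#' label fractions as rows and methods as columns.
#'
#' @param object A `cssl_grid`.
#' @param ... Unused.
#' @return A tibble in wide layout with `mean +/- sd` strings per cell.
#' @export
summary.cssl_grid <- function(object, ...) {
  object$cells |>
    dplyr::mutate(cell = sprintf("%.1f ± %.1f", .data$mean_acc,
                                 .data$sd_acc)) |>
    dplyr::select("label_fraction", "snr", "method", "cell") |>
    tidyr::pivot_wider(names_from = "method", values_from = "cell") |>
    dplyr::arrange(dplyr::desc(.data$label_fraction))
}

#' @importFrom rlang .data
#' @method autoplot cssl_pretrain
#' @export
autoplot.cssl_pretrain <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$mean_loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean contrastive loss",
                  title = sprintf("%s pretraining", object$method)) +
    ggplot2::theme_minimal()
}

#' @method autoplot cssl_classifier
#' @export
autoplot.cssl_classifier <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_acc"),
                           names_to = "metric")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot cssl_grid
#' @export
autoplot.cssl_grid <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$label_fraction, y = .data$mean_acc,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_acc - .data$sd_acc,
      ymax = .data$mean_acc + .data$sd_acc)) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%d%%", round(100 * x))) +
    ggplot2::labs(x = "labelled fraction of the training set",
                  y = "test accuracy (%)", colour = NULL) +
    ggplot2::theme_minimal()
}
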