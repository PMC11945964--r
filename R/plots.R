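#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve of a metrics report
#'
#' @param object a `metrics_report` from [evaluate_scores()].
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  if (is.null(object$roc)) abort_argument("report carries no ROC curve")
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate (1 - specificity)",
                  y = "true positive rate (sensitivity)",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Training history curves
#'
#' @param object an `ebus_fit` or `ebus_fusion_fit`.
#' @param ... ignored.
#' @return a ggplot of train/validation loss by epoch.
#' @method autoplot ebus_fit
#' @export
autoplot.ebus_fit <- function(object, ...) plot_history(object$history, object$best_epoch)

#' @rdname autoplot.ebus_fit
#' @method autoplot ebus_fusion_fit
#' @export
autoplot.ebus_fusion_fit <- function(object, ...) plot_history(object$history, object$best_epoch)

plot_history <- function(history, best_epoch = NULL) {
  long <- tidyr::pivot_longer(history[, c("epoch", "train_loss", "valid_loss")],
                              -"epoch", names_to = "series", values_to = "loss")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                          colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(train_loss = "#878787", valid_loss = "#B2182B")) +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(best_epoch) && best_epoch > 0)
    p <- p + ggplot2::geom_vline(xintercept = best_epoch, linetype = "dotted")
  p
}

#' Display an EBUS frame or branch image
#'
#' @param img `H x W` or `H x W x 3` array in `[0, 255]`.
#' @param title optional plot title.
#' @return a ggplot.
#' @export
plot_frame <- function(img, title = NULL) {
  if (length(dim(img)) == 3) img <- to_grayscale(img)
  df <- expand.grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none",
                   plot.title = ggplot2::element_text(hjust = 0.5))
}
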