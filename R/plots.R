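# ggplot2 visualisations for phantoms, evaluation reports and FS traces.

image_df <- function(image, value = "intensity") {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(image)), times = ncol(image)),
    col = rep(seq_len(ncol(image)), each = nrow(image)),
    v = as.vector(image))
  names(df)[3] <- value
  df
}

#' Plot a grayscale image
#'
#' Raster plot with the image origin at the top-left, as in the pixel
#' coordinate convention.
#'
#' @param image Grayscale matrix.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_gray <- function(image, title = NULL) {
  df <- image_df(image)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phantom with its ground-truth mask outlines
#'
#' Pectoral outline in red, lesion in yellow, label artifacts in cyan.
#'
#' @param object A `phantom` from [generate_phantom()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom <- function(object, ...) {
  p <- plot_gray(object$image,
                 title = sprintf("phantom (%s)",
                                 if (object$class_label == 1) "abnormal"
                                 else "normal"))
  overlay <- function(p, mask, colour) {
    if (!any(mask)) return(p)
    df <- image_df(mask * 1, value = "m")
    p + ggplot2::geom_contour(
      data = df, ggplot2::aes(x = .data$col, y = .data$row, z = .data$m),
      inherit.aes = FALSE, breaks = 0.5, colour = colour, linewidth = 0.3)
  }
  p <- overlay(p, object$pectoral_mask, "red")
  p <- overlay(p, object$lesion_mask, "yellow")
  overlay(p, object$label_mask, "cyan")
}

#' Plot the ROC curve of an evaluation report
#'
#' Uses the pooled held-out scores across all folds.
#'
#' @param object An `eval_report` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  pts <- roc_points(object$scores, object$truth)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a feature-selection search trace
#'
#' Objective against evaluation order, coloured by subset size.
#'
#' @param object An `fs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$objective,
                                   colour = factor(.data$size))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Evaluation", y = "CV accuracy", colour = "subset size",
                  title = object$method) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
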