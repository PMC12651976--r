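#' Plot the optimizer's best-fitness trajectory
#'
#' @param object An `hgwo_pso` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hgwo_pso <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$iteration, y = .data$best_f)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::labs(x = "Iteration", y = "Best wrapper fitness F",
                  title = "HGWO-PSO convergence",
                  subtitle = sprintf("%d/%d features selected, F = %.4f",
                                     sum(object$best_mask), object$d,
                                     object$best_fitness$f)) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heatmap
#'
#' @param object A [confusion()] matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "Predicted class", y = "True class") +
    ggplot2::theme_minimal()
}

#' Plot the model comparison of an experiment
#'
#' @param object A `comparison_report`.
#' @param ... Unused.
#' @return A ggplot of held-out accuracy and macro-F1 per model.
#' @export
autoplot.comparison_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$comparison[c("model", "accuracy", "f1")],
                            cols = c("accuracy", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Held-out value", fill = NULL,
                  title = "Model comparison") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Display a phantom image
#'
#' @param object An [new_image2d()] matrix.
#' @param ... Unused.
#' @return A ggplot raster of the image.
#' @export
autoplot.image2d <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object)), col = seq_len(ncol(object)))
  df$value <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
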