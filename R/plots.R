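#' Plot a grayscale image
#'
#' Renders an intensity matrix as a ggplot raster in radiological
#' convention (row 1 at the top), gray palette from black (0) to white (1).
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_image <- function(img, title = NULL) {
  check_gray_image(img)
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$intensity <- as.vector(t(img))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none",
                   plot.title = ggplot2::element_text(hjust = 0.5))
}

#' @exportS3Method
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpf, .data$tpf)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "False positive fraction",
      y = "True positive fraction",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$auc)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA,
                          fill = "#d1e5f0") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6, size = 1.5) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = NULL, y = "AUC per iteration",
                  title = object$comparison) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.eval_report_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$auc)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA,
                          fill = "#d1e5f0") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1.2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = NULL, y = "AUC per iteration",
                  title = "Artifact recognition across comparisons") +
    ggplot2::theme_minimal()
}
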