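# ggplot2 display methods for the package's result types.

#' Plot a height raster
#'
#' @param object An `lp_raster`.
#' @param z_min,z_max Height range for the fill scale, metres.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lp_raster <- function(object, z_min = NULL, z_max = NULL, ...) {
  df <- tidy.lp_raster(object)
  rng <- range(df$z, finite = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cy, y = .data$cx, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(z_min %||% rng[1], z_max %||% rng[2]),
                                  oob = scales_squish, name = "height (m)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "axis 2 (m)", y = "axis 1 (m)") +
    ggplot2::theme_minimal()
}

# minimal squish so we need not depend on scales directly
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot a classification confusion matrix
#'
#' @param object An `lp_eval` report.
#' @param ... Unused.
#' @return A ggplot heat map of the confusion matrix.
#' @export
autoplot.lp_eval <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "truth", fill = "count") +
    ggplot2::theme_minimal()
}

#' Plot training history curves
#'
#' @param history Tibble from [train_model()]'s `history`.
#' @return A ggplot of loss and accuracy per epoch.
#' @export
plot_history <- function(history) {
  long <- tidyr::pivot_longer(history, -"epoch",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ ifelse(grepl("loss", metric), "loss", "accuracy"),
                        scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot per-plot lodging indices against the class thresholds
#'
#' @param plots Labelled plot tibble (columns `li`, `class`).
#' @param thresholds An [lodging_thresholds()].
#' @return A ggplot.
#' @export
plot_lodging_index <- function(plots, thresholds) {
  ggplot2::ggplot(plots, ggplot2::aes(x = .data$li, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = thresholds$boundaries, linetype = 2) +
    ggplot2::labs(x = "lodging index", y = "plots") +
    ggplot2::theme_minimal()
}
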