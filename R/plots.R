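#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic Petri-dish scene
#'
#' Renders the RGB image with the annotated bounding boxes overlaid.
#'
#' @param object a `petri_scene`.
#' @param boxes draw the annotation boxes?
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.petri_scene <- function(object, boxes = TRUE, ...) {
  img <- object$image
  h <- dim(img)[1]
  df <- expand.grid(y = seq_len(h) - 1, x = seq_len(dim(img)[2]) - 1)
  df$fill <- grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                            as.vector(img[, , 3]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  b <- object$annotation$boxes
  if (boxes && nrow(b) > 0) {
    p <- p + ggplot2::geom_rect(
      data = b,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = .data$y_min, ymax = .data$y_max),
      inherit.aes = FALSE, fill = NA, colour = "dodgerblue", linewidth = 0.3)
  }
  p
}

#' Plot a density map
#'
#' @param object a `density_target` or bare matrix.
#' @param ... unused.
#' @return a ggplot raster of the map.
#' @export
autoplot.density_target <- function(object, ...) {
  plot_density_map(object$map) +
    ggplot2::labs(title = sprintf("density target (count %.2f)", object$count))
}

#' @rdname autoplot.density_target
#' @param map numeric matrix.
#' @export
plot_density_map <- function(map) {
  df <- expand.grid(row = seq_len(nrow(map)) - 1, col = seq_len(ncol(map)) - 1)
  df$value <- as.vector(map)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "density")
}

#' Plot a training history
#'
#' Loss curves and the mean-beta trajectory per epoch.
#'
#' @param object an `sndm_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sndm_fit <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss", "val_count_mae",
                          "mean_beta"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Plot predictions against ground truth
#'
#' The classic diagnostic: predicted versus true counts with 1-sigma error
#' bars; ideal predictions fall on the identity line.
#'
#' @param object an `sndm_eval`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sndm_eval <- function(object, ...) {
  r <- object$records
  ggplot2::ggplot(r, ggplot2::aes(x = .data$n, y = .data$n_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "orange") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$n_hat - .data$sigma,
                                        ymax = .data$n_hat + .data$sigma),
                           width = 0, colour = "grey30") +
    ggplot2::geom_point(colour = "steelblue", size = 1.2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "true count", y = "predicted count",
                  title = sprintf("predicted vs. truth (%s)", object$method))
}
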