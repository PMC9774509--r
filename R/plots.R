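# ggplot2 autoplot methods for the package's result objects.

#' @describeIn train_network Training and validation loss/accuracy curves.
#' @param object A fitted object.
#' @method autoplot koi_cnn_fit
#' @export
autoplot.koi_cnn_fit <- function(object, ...) {
  long <- object$traces |>
    tidyr::pivot_longer(-"epoch", names_to = c("split", "metric"),
                        names_sep = "_", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_predictions Confusion-matrix heatmap.
#' @param object A `koi_eval`.
#' @method autoplot koi_eval
#' @export
autoplot.koi_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted class", y = "true class", fill = "count") +
    ggplot2::theme_minimal()
}

#' @describeIn grad_cam Heatmap of the class activation map.
#' @param object A `koi_cam`.
#' @param ... Unused.
#' @method autoplot koi_cam
#' @export
autoplot.koi_cam <- function(object, ...) {
  v <- object$values
  df <- expand.grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  df$value <- as.vector(v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("class %d", object$target_class)) +
    ggplot2::theme_void()
}

#' Overlay a class activation map on its image
#'
#' @param cam A `koi_cam`.
#' @param image The `(H, W, 3)` input image.
#' @param alpha Blend weight of the heatmap.
#' @return `(H, W, 3)` blended array, suitable for [png::writePNG()].
#' @export
cam_overlay <- function(cam, image, alpha = 0.5) {
  S <- nrow(cam$values)
  if (!all(dim(image)[1:2] == S)) image <- resize_bilinear_cpp(image, S, S)
  v <- cam$values
  # simple blue-to-red colormap
  heat <- array(0, c(S, S, 3))
  heat[, , 1] <- v
  heat[, , 3] <- 1 - v
  clamp01((1 - alpha) * image + alpha * heat)
}
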