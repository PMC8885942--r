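# ggplot2 displays for the result objects.

#' @export
autoplot.knn_k_selection <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::scale_x_continuous(breaks = object$curve$k) +
    ggplot2::labs(x = "k (neighbors)", y = "leave-one-out accuracy",
                  title = sprintf("Accuracy plot: chosen k = %d", object$k)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.experiment_summary <- function(object, ...) {
  sel <- structure(list(k = object$k, curve = object$curve, n = object$n_train),
                   class = "knn_k_selection")
  autoplot(sel) +
    ggplot2::labs(subtitle = sprintf(
      "test accuracy %.3f | sensitivity %.3f | specificity %.3f",
      object$accuracy, object$sensitivity, object$specificity))
}

#' Display a lesion image with an optional mask outline
#'
#' @param image Integer RGB array or a `lesion_case` (whose ground-truth mask
#'   is then drawn unless `mask` is supplied).
#' @param mask Optional logical mask whose boundary is outlined.
#' @return A ggplot object.
#' @export
plot_lesion <- function(image, mask = NULL) {
  if (inherits(image, "lesion_case")) {
    if (is.null(mask)) mask <- image$mask
    image <- image$image
  }
  assert_rgb(image)
  if (!is.null(mask)) image <- mask_overlay(image, assert_mask(mask))
  H <- dim(image)[1]; W <- dim(image)[2]
  ras <- grDevices::as.raster(image / 255)
  ggplot2::ggplot(data.frame(x = c(0, W), y = c(0, H))) +
    ggplot2::annotation_raster(ras, xmin = 0, xmax = W, ymin = 0, ymax = H) +
    ggplot2::scale_x_continuous(limits = c(0, W), expand = c(0, 0)) +
    ggplot2::scale_y_continuous(limits = c(0, H), expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
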