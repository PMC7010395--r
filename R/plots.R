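#' Plot a planar curve
#'
#' Convenience ggplot of a curve in image coordinates (y grows downward),
#' optionally with keypoints highlighted.
#'
#' @param curve a [planar_curve()].
#' @param keypoints optional `keypoint_set` (indices into the curve).
#' @return a ggplot object.
#' @export
plot_curve <- function(curve, keypoints = NULL) {
  df <- tibble::tibble(x = curve$points[, 1L], y = curve$points[, 2L])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (!is.null(keypoints) && nrow(keypoints) > 0L) {
    kp <- df[keypoints$index, , drop = FALSE]
    kp$prominence <- keypoints$prominence
    p <- p + ggplot2::geom_point(data = kp,
                                 ggplot2::aes(size = .data$prominence),
                                 colour = "red", alpha = 0.8)
  }
  p
}

#' @export
autoplot.detection_evaluation <- function(object, ...) {
  df <- object$pr
  df$t <- factor(df$t)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = .data$t)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(colour = "quality\nthreshold",
                  title = sprintf("Detection PR surface (AP_vol = %.3f)",
                                  object$ap_vol)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.identification_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$pr,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("Identification PR (AP = %.3f, mAP = %.3f)",
                                  object$ap, object$map)) +
    ggplot2::theme_minimal()
}

#' Heatmap of per-bin fin-space distinctiveness
#'
#' @param distinct a [measure_bin_distinctiveness()] table.
#' @return a ggplot object (spatial bin x scale bin, facetted by type).
#' @export
plot_bin_distinctiveness <- function(distinct) {
  ggplot2::ggplot(distinct,
                  ggplot2::aes(x = .data$spatial_bin, y = .data$scale_bin,
                               fill = .data$ap)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~dtype) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "spatial bin (partition run)", y = "scale bin",
                  fill = "AP") +
    ggplot2::theme_minimal()
}
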