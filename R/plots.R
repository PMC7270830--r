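#' Plot predicted against measured plot DMY
#'
#' Scatter of measured on predicted kg/plot with the fitted regression line
#' and the 1:1 line, annotated with slope, R-squared and RMSE.
#'
#' @param object a `dmy_validation` from [validate_predictions()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dmy_validation <- function(object, ...) {
  lab <- sprintf("slope = %.2f,  R² = %.2f,  RMSE = %.2f",
                 object$slope, object$r_squared, object$rmse_raw)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$predicted, y = .data$measured)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "Predicted DMY (kg/plot)",
                  y = "Measured DMY (kg/plot)", subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Plot a projection profile with its detected troughs
#'
#' @param values numeric profile.
#' @param troughs tibble from [process_profile()].
#' @return a ggplot.
#' @export
plot_profile <- function(values, troughs = NULL) {
  d <- tibble::tibble(i = seq_along(values), value = values)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pixel index", y = "profile sum") +
    ggplot2::theme_minimal()
  if (!is.null(troughs) && nrow(troughs)) {
    p <- p +
      ggplot2::geom_vline(xintercept = troughs$center, colour = "firebrick") +
      ggplot2::geom_vline(xintercept = c(troughs$left, troughs$right),
                          colour = "steelblue", linetype = "dotted")
  }
  p
}

#' Plot row boxes and plant centres over the image extent
#'
#' @param boxes row-box tibble (pixel rectangles).
#' @param centers optional tibble of plant centres (`col`, `row`).
#' @return a ggplot (y axis flipped to image orientation).
#' @export
plot_row_boxes <- function(boxes, centers = NULL) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = boxes,
                       ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                                    ymin = .data$y0, ymax = .data$y1),
                       fill = NA, colour = "forestgreen", linewidth = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
  if (!is.null(centers) && nrow(centers)) {
    p <- p + ggplot2::geom_point(data = centers,
                                 ggplot2::aes(x = .data$col, y = .data$row),
                                 size = 0.3, colour = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
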