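#' Contour plot of a fitted response surface
#'
#' Draws the predicted response over a grid of two factors, holding the
#' remaining factors at their centre levels.
#'
#' @param object An `sfe_surface`.
#' @param x,y Factor names for the axes; default the first two factors.
#' @param n Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfe_surface <- function(object, x = NULL, y = NULL, n = 80, ...) {
  fac <- object$factors
  x <- x %||% fac$name[1]
  y <- y %||% fac$name[2]
  if (!all(c(x, y) %in% fac$name)) abort("x and y must be factor names")
  grid <- expand.grid(
    seq(fac$low[fac$name == x], fac$high[fac$name == x], length.out = n),
    seq(fac$low[fac$name == y], fac$high[fac$name == y], length.out = n)
  )
  names(grid) <- c(x, y)
  for (f in setdiff(fac$name, c(x, y))) grid[[f]] <- fac$center[fac$name == f]
  grid$.fitted <- predict(object, grid, warn_extrapolation = FALSE)
  ggplot2::ggplot(grid, ggplot2::aes(.data[[x]], .data[[y]], z = .data$.fitted)) +
    ggplot2::geom_contour_filled(bins = 12) +
    ggplot2::labs(
      x = paste0(x, " (", fac$unit[fac$name == x], ")"),
      y = paste0(y, " (", fac$unit[fac$name == y], ")"),
      fill = paste0(object$response, " (", object$response_scale, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Observed curve with the fitted kinetic model
#'
#' @param object An `sfe_kinfit`.
#' @param n Number of points on the fitted line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfe_kinfit <- function(object, n = 200, ...) {
  tt <- seq(min(object$curve$time), max(object$curve$time), length.out = n)
  line <- tibble::tibble(time = tt, yield = predict(object, newtimes = tt))
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$time / 3600, .data$yield)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::labs(x = "time (h)", y = "cumulative yield",
                  title = paste0("Fitted ", object$model, " model")) +
    ggplot2::theme_minimal()
}

#' Plot an extraction curve
#'
#' @param curve Tibble with `time` (s) and `yield`.
#' @return A ggplot object.
#' @export
plot_extraction_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$time / 3600, .data$yield)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time (h)", y = "cumulative yield") +
    ggplot2::theme_minimal()
}
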