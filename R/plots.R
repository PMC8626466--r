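# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a mosaic as a raster image
#'
#' @param object an `sbnp_mosaic`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sbnp_mosaic
#' @export
autoplot.sbnp_mosaic <- function(object, ...) {
  df <- tidyr::expand_grid(y = seq_len(nrow(object$image)),
                           x = seq_len(ncol(object$image)))
  df$intensity <- as.vector(t(object$image))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "gray") +
    ggplot2::theme_minimal()
}

#' Plot a traced nerve graph
#'
#' Centerline polylines in micrometre coordinates with branch points
#' marked.
#'
#' @param object a `nerve_graph`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot nerve_graph
#' @export
autoplot.nerve_graph <- function(object, ...) {
  df <- purrr::imap_dfr(object$edges_um, function(p, i)
    tibble::tibble(edge = i, x = p[, 1], y = p[, 2]))
  g <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        group = .data$edge)) +
    ggplot2::geom_path(linewidth = 0.3, colour = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
  if (nrow(object$branch_points_um) > 0) {
    bp <- tibble::tibble(x = object$branch_points_um[, 1],
                         y = object$branch_points_um[, 2])
    g <- g + ggplot2::geom_point(data = bp,
                                 ggplot2::aes(.data$x, .data$y),
                                 inherit.aes = FALSE,
                                 colour = "red", size = 0.8)
  }
  g
}

#' Bland-Altman plot
#'
#' Pair means against differences, with the mean difference (solid) and
#' the 95% limits of agreement (dashed).
#'
#' @param object a [bland_altman()] object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower,
                                       object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of observers (cells/mm²)",
                  y = "difference (cells/mm²)") +
    ggplot2::theme_minimal()
}
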