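# ggplot2 views of the pipeline objects --------------------------------------

#' Plot a transduction profile
#'
#' Fraction of transduced cells versus longitudinal position, one line per
#' cell type, styled like the usual base-to-apex cochleogram graphs.
#'
#' @param object A `transduction_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transduction_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$position_um, y = .data$fraction,
                               colour = .data$cell_type)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_y_continuous(labels = function(b) sprintf("%.0f%%", 100 * b)) +
    ggplot2::labs(x = "Position along cochlear axis, base to apex (um)",
                  y = "Transduction rate", colour = "Cell type") +
    ggplot2::theme_minimal()
}

#' Plot a cochleogram (smoothed transduced-cell density)
#'
#' @param object A `cochleogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cochleogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$position_um,
                               y = .data$density_cells_per_um,
                               colour = .data$cell_type)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Position along cochlear axis, base to apex (um)",
                  y = "Transduced cells / um", colour = "Cell type") +
    ggplot2::theme_minimal()
}

#' Plot a fitted cochlear axis
#'
#' The fitted curve with the operator's control points overlaid; useful for
#' checking the delineation and the interpolation.
#'
#' @param object A `cochlea_axis`.
#' @param cells Optional annotation data frame (`x`, `y`, `cell_type`) to
#'   overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cochlea_axis <- function(object, cells = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey40") +
    ggplot2::geom_point(data = object$polyline, shape = 3, colour = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
  if (!is.null(cells)) {
    p <- p + ggplot2::geom_point(
      data = cells, ggplot2::aes(colour = .data$cell_type), size = 0.6) +
      ggplot2::labs(colour = "Cell type")
  }
  p
}
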