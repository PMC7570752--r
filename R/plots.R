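#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cluster label image
#'
#' Pseudo-color reconstruction of the spectral image from its class
#' labels, one fixed color per class id (shared across images of a common
#' k-means).
#'
#' @param object A `label_image`.
#' @param colors Optional color vector by class id (defaults to the fixed
#'   package palette).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.label_image <- function(object, colors = NULL, ...) {
  df <- tidy(object)
  df <- df[df$class_id >= 0, ]
  df$class_id <- factor(df$class_id, levels = 0:(object$k - 1))
  cols <- colors %||% class_palette(object$k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class_id)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = cols, drop = FALSE, name = "class") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$sample_id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot centroid spectra of a k-means model
#'
#' @param object A `kmeans_model`.
#' @param ... Unused.
#' @return A ggplot of absorbance vs wavenumber, one line per class.
#' @export
autoplot.kmeans_model <- function(object, ...) {
  df <- tidy(object)
  df$class_id <- factor(df$class_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$absorbance,
                                   color = .data$class_id)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = class_palette(object$k), name = "class") +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance (AU)") +
    ggplot2::theme_minimal()
}

#' Plot a second-derivative spectrum with its picked bands
#'
#' @param object A `derivative_spectrum`.
#' @param bands Optional `band_table` to mark (vertical lines at picked
#'   positions).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.derivative_spectrum <- function(object, bands = NULL, ...) {
  df <- tibble::tibble(wavenumber = as.numeric(object$axis),
                       d2 = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$d2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)),
                  y = expression(d^2 * A / d * nu^2)) +
    ggplot2::theme_minimal()
  if (!is.null(bands) && nrow(bands)) {
    p <- p + ggplot2::geom_vline(xintercept = bands$position,
                                 linetype = "dashed", color = "grey50")
  }
  p
}

#' Scatter plot of DIA vs spectral fibrosis percentages
#'
#' One panel per clustering granularity k, mirroring the paired-method
#' correlation analysis.
#'
#' @param object A `run_report` from [run_whole_sample()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.run_report <- function(object, ...) {
  kcols <- grep("^spectral_k[0-9]+$", names(object$areas), value = TRUE)
  df <- tidyr::pivot_longer(object$areas, dplyr::all_of(kcols),
                            names_to = "k", values_to = "spectral")
  df$k <- sub("spectral_k", "k = ", df$k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dia_percent, y = .data$spectral,
                                   color = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~k) +
    ggplot2::labs(x = "Fibrosis area by DIA (%)",
                  y = "Fibrosis area by k-means (%)") +
    ggplot2::theme_minimal()
}
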