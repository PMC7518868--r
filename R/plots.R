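#' Heatmap of a parcel matrix
#'
#' Parcels ordered as stored; values on a symmetric diverging scale for
#' correlation-like kinds.
#'
#' @param object A `parcel_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parcel_matrix <- function(object, ...) {
  p <- nrow(object$values)
  df <- tidyr::expand_grid(i = seq_len(p), j = seq_len(p))
  df$value <- object$values[cbind(df$i, df$j)]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = object$kind) +
    ggplot2::theme_minimal()
  if (object$kind != "distance") {
    lim <- max(abs(object$values[is.finite(object$values)]))
    gg <- gg + ggplot2::scale_fill_gradient2(limits = c(-lim, lim))
  }
  gg
}

#' Gradient scatter in embedding space
#'
#' First two gradients against each other, colored by the first.
#'
#' @param object A `gradient_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gradient_set <- function(object, ...) {
  df <- tibble::tibble(
    G1 = object$coords[, 1],
    G2 = if (ncol(object$coords) >= 2) object$coords[, 2] else 0
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$G1, y = .data$G2, color = .data$G1)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(
      x = sprintf("G1 (%.0f%% var)", 100 * object$variance_explained[1]),
      y = if (ncol(object$coords) >= 2) {
        sprintf("G2 (%.0f%% var)", 100 * object$variance_explained[2])
      } else {
        ""
      }
    ) +
    ggplot2::theme_minimal()
}

#' Mean source values within and between gradient bins
#'
#' @param object A `gradient_bins`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gradient_bins <- function(object, ...) {
  n <- object$n_bins
  df <- tidyr::expand_grid(bin_i = seq_len(n), bin_j = seq_len(n))
  df$value <- object$bin_matrix[cbind(df$bin_i, df$bin_j)]
  lim <- max(abs(df$value), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_j, y = .data$bin_i, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(limits = c(-lim, lim)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "gradient bin", y = "gradient bin", fill = "mean") +
    ggplot2::theme_minimal()
}

#' Parcel map on the flattened sphere
#'
#' Plots a per-parcel value at each parcel centroid, using an azimuthal view
#' per hemisphere (y against z, split by hemisphere facet).
#'
#' @param geom A `parcel_geometry`.
#' @param values Numeric vector, one value per parcel.
#' @param name Legend title.
#' @return A ggplot object.
#' @export
plot_parcel_map <- function(geom, values, name = "value") {
  df <- tibble::tibble(
    y = geom$centroid[, 2], z = geom$centroid[, 3],
    hemisphere = geom$hemisphere, value = values
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$z, color = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~hemisphere) +
    ggplot2::scale_color_viridis_c(name = name) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "posterior - anterior", y = "inferior - superior") +
    ggplot2::theme_minimal()
}
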