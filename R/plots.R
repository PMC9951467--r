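#' Plot relative density over time for a study
#'
#' Group means with SEM ribbons, faceted by layer scope — the standard
#' presentation of a longitudinal vasoconstriction experiment.
#'
#' @param object A `pam_study`.
#' @param layers Layer scopes to show.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot pam_study
#' @export
autoplot.pam_study <- function(object, layers = LAYER_SCOPES, ...) {
  df <- dplyr::filter(object$summaries, .data$layer %in% layers)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$mean_relative,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_relative - .data$sem_relative,
      ymax = .data$mean_relative + .data$sem_relative),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~layer) +
    ggplot2::labs(x = "time (min)", y = "relative vascular density",
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}

#' Plot a depth histogram with its layer boundaries
#'
#' @param object A [depth_histogram()].
#' @param bounds Optional [segment_layers()] result to overlay.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot pam_depth_histogram
#' @export
autoplot.pam_depth_histogram <- function(object, bounds = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_um)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), width = object$dz,
                      fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "black") +
    ggplot2::labs(x = "depth below surface (um)", y = "vessel voxel count") +
    ggplot2::theme_minimal()
  if (!is.null(bounds)) {
    um <- function(i) (i - 1) * bounds$dz
    p <- p +
      ggplot2::geom_vline(xintercept = c(um(bounds$d_pd), um(bounds$d_hd)),
                          colour = c("red", "blue")) +
      ggplot2::geom_vline(xintercept = c(um(bounds$z_pd_rd),
                                         um(bounds$z_rd_hd)),
                          linetype = "dashed", colour = "grey40")
  }
  p
}

#' Render a MAP image as a ggplot raster
#'
#' @param map A [pam_map()] (or matrix).
#' @param spacing_um Pixel spacing `c(dx, dy)` for axis scaling.
#' @return A ggplot.
#' @export
plot_map <- function(map, spacing_um = c(1, 1)) {
  v <- if (inherits(map, "pam_map")) map$values else map
  df <- tidyr::expand_grid(x = seq_len(nrow(v)), y = seq_len(ncol(v)))
  df$value <- as.vector(v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * spacing_um[1],
                                   y = .data$y * spacing_um[2],
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "amplitude") +
    ggplot2::theme_minimal()
}

#' Plot centroid-depth displacement over time
#'
#' @param centroids Centroid tibble from a study or [analyze_subject()].
#' @return A ggplot of group mean displacement with SEM ribbons.
#' @export
plot_centroid_displacement <- function(centroids) {
  df <- centroids |>
    dplyr::group_by(.data$group, .data$t_min) |>
    dplyr::summarise(mean_disp = mean(.data$displacement_um),
                     sem = if (dplyr::n() >= 2) {
                       sd(.data$displacement_um) / sqrt(dplyr::n())
                     } else NA_real_,
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$mean_disp,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_disp - .data$sem,
                                      ymax = .data$mean_disp + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)",
                  y = "centroid depth displacement (um)") +
    ggplot2::theme_minimal()
}
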