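# ggplot2 display of embeddings, unrolled outlines and diameter profiles.

ellipse_path <- function(center_1, center_2, semi_major, semi_minor, tilt_rad,
                         n = 181) {
  t <- seq(0, 2 * pi, length.out = n)
  ct <- cos(tilt_rad); st <- sin(tilt_rad)
  ex <- semi_major * cos(t); ey <- semi_minor * sin(t)
  tibble::tibble(umap1 = center_1 + ct * ex - st * ey,
                 umap2 = center_2 + st * ex + ct * ey)
}

#' Plot a UMAP embedding with per-group bounding ellipses
#'
#' @param object A `vm_embedding` from [embed_shapes()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vm_embedding <- function(object, ...) {
  paths <- object$ellipses |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ellipse_path(.x$center_1, .x$center_2,
                                      .x$semi_major, .x$semi_minor,
                                      .x$tilt_rad)) |>
    dplyr::ungroup()
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(x = .data$umap1, y = .data$umap2,
                               colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.4) +
    ggplot2::geom_path(data = paths, linewidth = 0.6) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot unrolled cell outlines in the developed plane
#'
#' @param unrolled Tibble from [unroll_outlines()].
#' @param colour_by Optional column name to colour outlines by (defaults to
#'   `"group"` when present).
#' @return A ggplot (axial position vs arc-length coordinate, equal scales).
#' @export
plot_unrolled <- function(unrolled, colour_by = NULL) {
  check_columns(unrolled, c("cell_id", "x_um", "s_um"), "unrolled table")
  if (is.null(colour_by) && "group" %in% names(unrolled)) colour_by <- "group"
  closed <- unrolled |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~dplyr::bind_rows(.x, .x[1, ])) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(closed, ggplot2::aes(x = .data$x_um, y = .data$s_um,
                                            group = .data$cell_id))
  p <- if (is.null(colour_by)) {
    p + ggplot2::geom_path(linewidth = 0.3)
  } else {
    p + ggplot2::geom_path(ggplot2::aes(colour = .data[[colour_by]]),
                           linewidth = 0.3)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "axial position (µm)", y = "arc-length coordinate (µm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a diameter profile along the vessel
#'
#' @param object A `vm_diameter` from [measure_diameter()].
#' @param ... Unused.
#' @return A ggplot of diameter vs station with the mean as a dashed line.
#' @export
autoplot.vm_diameter <- function(object, ...) {
  ggplot2::ggplot(object$stations,
                  ggplot2::aes(x = .data$station_um, y = .data$diameter_um)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diameter, linetype = 2) +
    ggplot2::labs(x = "axial station (µm)", y = "diameter (µm)") +
    ggplot2::theme_minimal()
}
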