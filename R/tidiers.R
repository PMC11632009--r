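# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted cross-section conic
#'
#' @param x A `vm_conic`.
#' @param ... Unused.
#' @return One-row tibble with kind, center, semi-axes, tilt.
#' @export
tidy.vm_conic <- function(x, ...) {
  tibble::tibble(kind = x$kind,
                 center_y = x$center[1], center_z = x$center[2],
                 semi_axis_1 = x$semi_axes[1], semi_axis_2 = x$semi_axes[2],
                 tilt_deg = x$tilt * 180 / pi)
}

#' @rdname tidy.vm_conic
#' @export
glance.vm_conic <- function(x, ...) {
  tibble::tibble(fit_rms_um = x$fit_rms, n_points = x$n_points, kind = x$kind)
}

#' Tidy a fitted 2D cell ellipse
#'
#' @param x A `vm_ellipse2d`.
#' @param ... Unused.
#' @export
tidy.vm_ellipse2d <- function(x, ...) {
  tibble::tibble(a_um = x$a, b_um = x$b, xc_um = x$center[1],
                 sc_um = x$center[2], phi_deg = x$phi_deg,
                 elongation = x$a / x$b)
}

#' Tidy a Jensen-Shannon divergence result
#'
#' @param x A `vm_jsd`.
#' @param ... Unused.
#' @export
tidy.vm_jsd <- function(x, ...) {
  tibble::tibble(group_a = x$group_a %||% NA_character_,
                 group_b = x$group_b %||% NA_character_,
                 jsd = x$jsd, js_distance = x$js_distance)
}

#' @rdname tidy.vm_jsd
#' @export
glance.vm_jsd <- function(x, ...) {
  tibble::as_tibble(x$estimator)
}

#' Tidy a pairwise divergence matrix into its long pair table
#'
#' @param x A `vm_jsd_matrix`.
#' @param ... Unused.
#' @export
tidy.vm_jsd_matrix <- function(x, ...) x$pairs

#' Tidy an embedding into its coordinate table
#'
#' @param x A `vm_embedding`.
#' @param ... Unused.
#' @export
tidy.vm_embedding <- function(x, ...) x$coords

#' @rdname tidy.vm_embedding
#' @export
glance.vm_embedding <- function(x, ...) {
  tibble::as_tibble(x$settings)
}

#' Tidy a diameter profile into its station table
#'
#' @param x A `vm_diameter`.
#' @param ... Unused.
#' @export
tidy.vm_diameter <- function(x, ...) x$stations

#' @rdname tidy.vm_diameter
#' @export
glance.vm_diameter <- function(x, ...) {
  tibble::tibble(mean_diameter_um = x$mean_diameter,
                 n_stations = nrow(x$stations), direction = x$direction)
}
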