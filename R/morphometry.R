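# Per-cell shape parameters and vessel-level measurements.

#' Fit a 2D ellipse to an unrolled cell boundary
#'
#' Ellipse-constrained direct least-squares fit in the unrolled
#' (axial x, arc-length s) plane. `a >= b` is enforced by swapping axes, and
#' the major-axis angle `phi` is folded to \[0, 90\] degrees (an undirected
#' axis is only defined modulo 180 degrees).
#'
#' @param x,s Unrolled coordinates of one cell, micrometres.
#' @return A `vm_ellipse2d`: `a`, `b` (µm), `center` (xc, sc), `phi_deg`.
#' @export
fit_ellipse_2d <- function(x, s) {
  pts <- unique(cbind(x, s))
  if (nrow(pts) < 5) vm_stop("need at least 5 distinct points to fit an ellipse")
  sv <- svd(cbind(pts[, 1] - mean(pts[, 1]), pts[, 2] - mean(pts[, 2])), nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) vm_stop("cannot fit an ellipse to collinear points")
  coef <- fit_conic_ellipse(pts[, 1], pts[, 2])
  par <- conic_parameters(coef)
  if (par$kind != "ellipse") vm_stop("2D fit did not yield an ellipse")
  a <- par$semi_axes[1]; b <- par$semi_axes[2]; tilt <- par$tilt
  if (b > a) {
    tmp <- a; a <- b; b <- tmp
    tilt <- tilt + pi / 2
  }
  structure(list(a = a, b = b, center = par$center,
                 phi_deg = fold_angle(tilt * 180 / pi)),
            class = "vm_ellipse2d")
}

#' @export
print.vm_ellipse2d <- function(x, ...) {
  cat(sprintf("<vm_ellipse2d> a = %.3f µm, b = %.3f µm, center (%.2f, %.2f), phi = %.2f deg\n",
              x$a, x$b, x$center[1], x$center[2], x$phi_deg))
  invisible(x)
}

# One cell's shape record from its unrolled points.
shape_one_cell <- function(x, s, area_from) {
  ell <- fit_ellipse_2d(x, s)
  selfx <- polygon_self_intersects(x, s)
  area_poly <- polygon_area(x, s)
  area <- if (area_from == "polygon") area_poly else pi * ell$a * ell$b
  tibble::tibble(
    area_um2 = area,
    perimeter_um = polygon_perimeter(x, s),
    elongation = ell$a / ell$b,
    angle_deg = ell$phi_deg,
    a_um = ell$a, b_um = ell$b,
    xc_um = ell$center[1], sc_um = ell$center[2], phi_deg = ell$phi_deg,
    area_polygon_um2 = area_poly,
    area_ellipse_um2 = pi * ell$a * ell$b,
    self_intersecting = selfx,
    angle_low_confidence = ell$a / ell$b < 1.05)
}

#' Compute the four shape parameters for every cell
#'
#' For each unrolled cell: area (shoelace polygon area of the closed
#' outline by default, or the fitted-ellipse area pi*a*b), perimeter (closed
#' polyline length), elongation (a/b of the fitted ellipse) and angle of
#' alignment (major-axis angle to the vessel axis, folded to \[0, 90\]
#' degrees). Self-intersecting outlines are flagged, not rejected; angles of
#' near-circular cells (elongation < 1.05) are flagged low-confidence
#' because orientation is unidentifiable at circularity.
#'
#' @param unrolled Tibble from [unroll_outlines()] (`cell_id`,
#'   `point_index`, `x_um`, `s_um`, metadata carried through).
#' @param area_from `"polygon"` (default) or `"ellipse"`.
#' @return One row per cell: `cell_id`, `area_um2`, `perimeter_um`,
#'   `elongation`, `angle_deg`, ellipse internals (`a_um`, `b_um`, `xc_um`,
#'   `sc_um`, `phi_deg`), both area variants, warning flags, metadata.
#' @export
compute_shapes <- function(unrolled, area_from = c("polygon", "ellipse")) {
  area_from <- match.arg(area_from)
  check_columns(unrolled, c("cell_id", "point_index", "x_um", "s_um"),
                "unrolled table")
  meta <- intersect(c("group", vm_meta_cols), names(unrolled))
  unrolled |>
    dplyr::arrange(.data$cell_id, .data$point_index) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      rec <- shape_one_cell(df$x_um, df$s_um, area_from)
      dplyr::bind_cols(rec, df[1, meta, drop = FALSE])
    }) |>
    dplyr::ungroup()
}

#' Measure vessel diameters at axial stations
#'
#' At each station a conic is fitted to the transverse (y, z) coordinates of
#' the points in an axial slab around the station, and the diameter is the
#' full extent of the fitted conic along one transverse direction (default
#' `"y"`, the lateral imaging direction, matching diameters read off
#' maximum-intensity projections). The mean over stations is the per-vessel
#' average diameter.
#'
#' @param points Aligned point tibble (`x_um`, `y_um`, `z_um`).
#' @param stations Axial positions (µm) at which to measure.
#' @param direction `"y"` or `"z"`: transverse axis of the extent.
#' @param slab_um Axial slab thickness per station (µm).
#' @param kind Conic kind passed to [fit_cross_section()].
#' @return A `vm_diameter`: tibble of per-station diameters plus
#'   `mean_diameter`; see [tidy.vm_diameter()] / [glance.vm_diameter()].
#' @export
measure_diameter <- function(points, stations, direction = c("y", "z"),
                             slab_um = 4, kind = "ellipse") {
  direction <- match.arg(direction)
  check_columns(points, c("x_um", "y_um", "z_um"), "point table")
  if (!length(stations)) vm_stop("at least one station is required")
  d <- vapply(stations, function(st) {
    slab <- points[abs(points$x_um - st) <= slab_um / 2, ]
    if (nrow(slab) < 6) {
      vm_stop(sprintf("station %.1f µm is outside the data extent (only %d points in its slab)",
                      st, nrow(slab)))
    }
    m <- fit_cross_section(slab, kind)
    half <- if (direction == "y") {
      sqrt((m$semi_axes[1] * cos(m$tilt))^2 + (m$semi_axes[2] * sin(m$tilt))^2)
    } else {
      sqrt((m$semi_axes[1] * sin(m$tilt))^2 + (m$semi_axes[2] * cos(m$tilt))^2)
    }
    2 * half
  }, numeric(1))
  structure(list(stations = tibble::tibble(station_um = stations, diameter_um = d),
                 mean_diameter = mean(d), direction = direction),
            class = "vm_diameter")
}

#' @export
print.vm_diameter <- function(x, ...) {
  cat(sprintf("<vm_diameter> %d station(s), mean diameter %.3f µm (direction %s)\n",
              nrow(x$stations), x$mean_diameter, x$direction))
  invisible(x)
}

#' Count cells inside an axial window
#'
#' Counts distinct cells whose outline centroid falls in the half-open
#' axial window \[start, start + length). The 430 µm default mirrors the
#' standard counting window between the axial landmark vessels.
#'
#' @param points Outline tibble (`cell_id`, `x_um`).
#' @param window_start Window start, µm.
#' @param window_length Window length, µm (default 430).
#' @return Integer count (0 for an empty window).
#' @export
count_cells <- function(points, window_start = 0, window_length = 430) {
  check_columns(points, c("cell_id", "x_um"), "point table")
  cent <- points |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(cx = mean(.data$x_um), .groups = "drop")
  sum(cent$cx >= window_start & cent$cx < window_start + window_length)
}

#' Proliferation rate per cell
#'
#' Events are normalized to the cell count of the standard 430 µm window:
#' rate = events / cells. Vectorized over intervals/vessels.
#'
#' @param n_events Number of proliferation events per interval (>= 0).
#' @param n_cells Cell count per 430 µm of vessel (> 0).
#' @param interval_start,interval_end Optional interval bounds in hpf.
#' @return Tibble with `n_events`, `n_cells_per_430um`, `rate` (and the
#'   interval bounds when given).
#' @export
proliferation_rate <- function(n_events, n_cells,
                               interval_start = NULL, interval_end = NULL) {
  if (any(n_cells <= 0)) vm_stop("n_cells must be positive")
  if (any(n_events < 0)) vm_stop("n_events must be non-negative")
  out <- tibble::tibble(n_events = n_events, n_cells_per_430um = n_cells,
                        rate = n_events / n_cells)
  if (!is.null(interval_start)) out$interval_start_hpf <- interval_start
  if (!is.null(interval_end)) out$interval_end_hpf <- interval_end
  out
}
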