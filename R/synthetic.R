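# Synthetic vessels and cells with closed-form ground truth.
#
# Vessels are generalized cylinders (straight axis, constant conic cross
# section, optional linear taper). Untapered tubes develop isometrically
# onto the plane, so cells laid out as ellipses in the developed
# (axial, arc-length) plane have exact ground-truth area, perimeter,
# elongation and alignment angle -- the quantities the measurement pipeline
# is supposed to recover.

#' Specify a tubular vessel
#'
#' @param cross_section One of `"circle"`, `"ellipse"`, `"hyperbola_patch"`.
#'   A hyperbola patch is an open saddle-shaped wall segment (one branch).
#' @param radius_y,radius_z Cross-section semi-axes in micrometres
#'   (`radius_z` defaults to `radius_y`). For a hyperbola patch these are the
#'   transverse and conjugate semi-axes.
#' @param length Axial length in micrometres, or `NULL` to let
#'   [tessellate_cells()] size the vessel to fit its population.
#' @param axis_direction Unit 3-vector of the vessel axis (normalized
#'   internally; must be non-zero).
#' @param axis_origin 3D point on the axis, micrometres.
#' @param taper Fractional radius change per micrometre of axial distance
#'   (0 = untapered). A taper of 0.01/µm doubles the radius over 100 µm.
#' @param v_range Parameter range of the cross-section curve for open
#'   (hyperbola) patches.
#' @return A `vm_vessel_spec` list.
#' @export
#' @examples
#' vessel_spec(radius_y = 12.5, length = 430)
vessel_spec <- function(cross_section = c("circle", "ellipse", "hyperbola_patch"),
                        radius_y, radius_z = radius_y, length = NULL,
                        axis_direction = c(1, 0, 0), axis_origin = c(0, 0, 0),
                        taper = 0, v_range = c(-1.5, 1.5)) {
  cross_section <- match.arg(cross_section)
  if (!is.numeric(radius_y) || radius_y <= 0 || !is.numeric(radius_z) || radius_z <= 0) {
    vm_stop("vessel radii must be positive")
  }
  if (!is.null(length) && (!is.numeric(length) || length <= 0)) {
    vm_stop("vessel length must be positive (or NULL to auto-size)")
  }
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm < 1e-12) vm_stop("axis_direction must be a non-zero vector")
  structure(
    list(cross_section = cross_section, radius_y = radius_y, radius_z = radius_z,
         length = length, axis_direction = axis_direction / nrm,
         axis_origin = axis_origin, taper = taper, v_range = v_range),
    class = "vm_vessel_spec")
}

# Orthonormal frame whose first column is d (columns are world directions of
# the local x, y, z axes); right-handed.
axis_frame <- function(d) {
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- a - sum(a * d) * d
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(d[2] * e2[3] - d[3] * e2[2],
          d[3] * e2[1] - d[1] * e2[3],
          d[1] * e2[2] - d[2] * e2[1])
  cbind(d, e2, e3)
}

#' Build the parametric surface of a vessel
#'
#' Returns a surface object whose `$point(u, v)` maps axial coordinate `u`
#' (micrometres) and cross-section parameter `v` to 3D points: for a circle
#' of radius r, `point(0, 0)` is the point at local `(0, r, 0)`.
#'
#' @param spec A [vessel_spec()].
#' @return A `vm_vessel` surface object.
#' @export
make_vessel <- function(spec) {
  if (!inherits(spec, "vm_vessel_spec")) spec <- do.call(vessel_spec, spec)
  R <- axis_frame(spec$axis_direction)
  org <- spec$axis_origin
  pointfun <- function(u, v) {
    scale <- 1 + spec$taper * u
    ry <- spec$radius_y * scale
    rz <- spec$radius_z * scale
    local <- switch(spec$cross_section,
      circle = ,
      ellipse = cbind(u, ry * cos(v), rz * sin(v)),
      hyperbola_patch = cbind(u, ry * cosh(v), rz * sinh(v)))
    sweep(local %*% t(R), 2, org, `+`)
  }
  structure(list(spec = spec, point = pointfun), class = "vm_vessel")
}

# Arc length machinery of the cross-section curve at u = 0 (untapered
# sections are constant in u). Returns total developed width, s(v) and v(s).
cross_section_arclength <- function(spec) {
  if (spec$cross_section == "circle") {
    r <- spec$radius_y
    list(total = 2 * pi * r,
         s_of_v = function(v) r * v,
         v_of_s = function(s) s / r,
         closed = TRUE)
  } else if (spec$cross_section == "ellipse") {
    par <- list(kind = "ellipse", semi_axes = c(spec$radius_y, spec$radius_z),
                tilt = 0, center = c(0, 0))
    S <- conic_arclength_fun(par, 0, 2 * pi)
    vg <- seq(0, 2 * pi, length.out = 4097)
    sg <- S(vg)
    Vinv <- splinefun(sg, vg, method = "hyman")
    list(total = S(2 * pi), s_of_v = S, v_of_s = Vinv, closed = TRUE)
  } else {
    par <- list(kind = "hyperbola", semi_axes = c(spec$radius_y, spec$radius_z),
                tilt = 0, center = c(0, 0))
    S <- conic_arclength_fun(par, spec$v_range[1], spec$v_range[2])
    vg <- seq(spec$v_range[1], spec$v_range[2], length.out = 4097)
    sg <- S(vg)
    Vinv <- splinefun(sg, vg, method = "hyman")
    # open section: center the arc-length coordinate so s = 0 at mid-patch
    half <- S(spec$v_range[2]) / 2
    list(total = 2 * half,
         s_of_v = function(v) S(v) - half,
         v_of_s = function(s) Vinv(s + half),
         closed = FALSE)
  }
}

#' Specify a cell population for one group
#'
#' @param n_cells Number of cells (>= 1).
#' @param mean_area Mean cell area, µm².
#' @param area_cv Coefficient of variation of cell area (lognormal sizes).
#' @param mean_elongation Mean elongation (major/minor axis ratio, >= 1).
#' @param angle_mean,angle_sd Mean and s.d. (degrees) of the Gaussian draw of
#'   cell orientation relative to the vessel axis (folded to \[0, 90\] in the
#'   ground truth).
#' @param area_effect_multiplier Multiplies `mean_area`; a "+50%" group uses
#'   1.5 against a reference group's 1.0.
#' @param seed Integer seed for this group's draws.
#' @return A `vm_population_spec` list.
#' @export
population_spec <- function(n_cells, mean_area, area_cv = 0.2,
                            mean_elongation = 1.8, angle_mean = 25, angle_sd = 18,
                            area_effect_multiplier = 1, seed = 1L) {
  if (n_cells < 1) vm_stop("n_cells must be >= 1")
  if (mean_area <= 0) vm_stop("mean_area must be positive")
  if (mean_elongation < 1) vm_stop("mean_elongation must be >= 1")
  if (area_effect_multiplier <= 0) vm_stop("area_effect_multiplier must be positive")
  structure(
    list(n_cells = as.integer(n_cells), mean_area = mean_area, area_cv = area_cv,
         mean_elongation = mean_elongation, angle_mean = angle_mean,
         angle_sd = angle_sd, area_effect_multiplier = area_effect_multiplier,
         seed = as.integer(seed)),
    class = "vm_population_spec")
}

#' Tessellate a vessel surface into cells with known ground truth
#'
#' Cells are ellipses in the developed (axial u, arc-length s) plane, placed
#' on a non-overlapping grid of slots sized to the largest drawn cell. Cell
#' areas are lognormal with the requested mean (after the effect multiplier)
#' and CV, so group mean-area ratios converge to the multiplier ratio.
#' Requires an untapered vessel: generalized cylinders develop isometrically,
#' making the developed-plane ellipse area the exact geodesic area.
#'
#' @param vessel A `vm_vessel` (or [vessel_spec()]).
#' @param population A [population_spec()].
#' @return A `vm_cells` tibble: one row per cell with ground-truth columns
#'   (`true_area`, `true_perimeter`, `true_elongation`, `true_angle`,
#'   `axial_extent`, `angular_extent`) and placement internals; the vessel is
#'   attached as attribute `"vessel"`.
#' @export
tessellate_cells <- function(vessel, population) {
  if (inherits(vessel, "vm_vessel_spec")) vessel <- make_vessel(vessel)
  spec <- vessel$spec
  if (spec$taper != 0) {
    vm_stop("tessellate_cells requires an untapered vessel: only generalized cylinders develop isometrically, so ground-truth areas would be approximate on a tapered tube")
  }
  pop <- population
  set.seed(pop$seed)
  n <- pop$n_cells
  m_area <- pop$mean_area * pop$area_effect_multiplier
  sdlog <- sqrt(log(1 + pop$area_cv^2))
  areas <- rlnorm(n, meanlog = log(m_area) - sdlog^2 / 2, sdlog = sdlog)
  el_sdlog <- 0.3
  elong <- 1 + (pop$mean_elongation - 1) *
    rlnorm(n, meanlog = -el_sdlog^2 / 2, sdlog = el_sdlog)
  orient_deg <- rnorm(n, pop$angle_mean, pop$angle_sd)
  orient <- orient_deg * pi / 180
  A <- sqrt(areas * elong / pi)
  B <- sqrt(areas / (pi * elong))
  bu <- sqrt((A * cos(orient))^2 + (B * sin(orient))^2)
  bs <- sqrt((A * sin(orient))^2 + (B * cos(orient))^2)

  cs <- cross_section_arclength(spec)
  slot_u <- 2 * max(bu) * 1.05
  slot_s <- 2 * max(bs) * 1.05
  n_circ <- floor(cs$total / slot_s)
  if (n_circ < 1) {
    vm_stop(sprintf(
      "overcrowded tessellation: widest cell needs %.1f µm of circumference but the cross-section develops to only %.1f µm; reduce mean_area or enlarge the vessel",
      slot_s, cs$total))
  }
  n_axial <- ceiling(n / n_circ)
  required_length <- n_axial * slot_u
  if (is.null(spec$length)) {
    spec$length <- required_length
    vessel <- make_vessel(spec)
  } else if (required_length > spec$length) {
    achievable <- floor(spec$length / slot_u) * n_circ
    vm_stop(sprintf(
      "overcrowded tessellation: %d cells need %.1f µm of vessel length but only %.1f µm is available; achievable maximum is %d cells",
      n, required_length, spec$length, achievable))
  }

  idx <- seq_len(n) - 1L
  ring <- idx %% n_circ
  row_ax <- idx %/% n_circ
  u_c <- (row_ax + 0.5) * slot_u
  s_off <- if (cs$closed) 0 else -cs$total / 2
  s_c <- (ring + 0.5) * slot_s + s_off

  # exact perimeter of each developed-plane ellipse (numerical quadrature)
  perim <- vapply(seq_len(n), function(i) {
    par <- list(kind = "ellipse", semi_axes = c(A[i], B[i]), tilt = 0)
    conic_arclength_fun(par, 0, 2 * pi, n_grid = 1024)(2 * pi)
  }, numeric(1))

  r_eff <- cs$total / (2 * pi)
  out <- tibble::tibble(
    cell_id = sprintf("cell%04d", seq_len(n)),
    true_area = pi * A * B,
    true_perimeter = perim,
    true_elongation = elong,
    true_angle = fold_angle(orient_deg),
    axial_extent = 2 * bu,
    angular_extent = 2 * bs / r_eff,
    u_center = u_c, s_center = s_c,
    semi_major = A, semi_minor = B, orientation_rad = orient)
  attr(out, "vessel") <- vessel
  class(out) <- c("vm_cells", class(out))
  out
}

# Developed-plane boundary of one cell at ellipse parameters tvec,
# mapped to 3D through the vessel surface.
cell_boundary_3d <- function(vessel, row, tvec,
                             cs = cross_section_arclength(vessel$spec)) {
  co <- cos(row$orientation_rad); si <- sin(row$orientation_rad)
  ex <- row$semi_major * cos(tvec); ey <- row$semi_minor * sin(tvec)
  u <- row$u_center + co * ex - si * ey
  s <- row$s_center + si * ex + co * ey
  v <- cs$v_of_s(s)
  vessel$point(u, v)
}

#' Sample noisy traced outlines of tessellated cells
#'
#' Emulates manual tracing of cell boundaries: `n_points` ordered points per
#' cell at uniform arc-length spacing along the developed boundary (optionally
#' jittered), perturbed by isotropic 3D Gaussian noise.
#'
#' @param cells A `vm_cells` table from [tessellate_cells()].
#' @param n_points Points per outline (>= 8; conic and ellipse fits are
#'   underdetermined below that).
#' @param noise_sd Tracing noise s.d. in micrometres (isotropic, per point).
#' @param seed Integer seed.
#' @param jitter_spacing If `TRUE`, point spacing is uniformly jittered
#'   instead of exactly uniform in arc length.
#' @return Tibble of outline points: `cell_id`, `point_index`,
#'   `x_um`, `y_um`, `z_um`.
#' @export
sample_outline <- function(cells, n_points = 100, noise_sd = 0.2, seed = 1L,
                           jitter_spacing = FALSE) {
  if (n_points < 8) vm_stop("n_points must be >= 8 (conic and ellipse fits are underdetermined below 8 points)")
  vessel <- attr(cells, "vessel")
  if (is.null(vessel)) vm_stop("`cells` must come from tessellate_cells() (missing vessel attribute)")
  set.seed(seed)
  cs <- cross_section_arclength(vessel$spec)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    row <- cells[i, ]
    par <- list(kind = "ellipse", semi_axes = c(row$semi_major, row$semi_minor), tilt = 0)
    S <- conic_arclength_fun(par, 0, 2 * pi, n_grid = 1024)
    total <- S(2 * pi)
    tg <- seq(0, 2 * pi, length.out = 1025)
    Tinv <- splinefun(S(tg), tg, method = "hyman")
    s_targets <- seq(0, total, length.out = n_points + 1)[-(n_points + 1)]
    if (jitter_spacing) {
      step <- total / n_points
      s_targets <- (s_targets + runif(n_points, -0.3, 0.3) * step) %% total
      s_targets <- sort(s_targets)
    }
    tvec <- Tinv(s_targets)
    p3 <- cell_boundary_3d(vessel, row, tvec, cs)
    if (noise_sd > 0) {
      p3 <- p3 + matrix(rnorm(3 * n_points, 0, noise_sd), ncol = 3)
    }
    tibble::tibble(cell_id = row$cell_id, point_index = seq_len(n_points),
                   x_um = p3[, 1], y_um = p3[, 2], z_um = p3[, 3])
  })
  dplyr::bind_rows(res)
}

#' Define one cohort group
#'
#' @param name Group label (must be unique within a cohort).
#' @param vessel A [vessel_spec()].
#' @param population A [population_spec()].
#' @param vessel_type `"artery"` or `"vein"`.
#' @param region `"trunk"` or `"tail"`.
#' @param stage_hpf Developmental stage, hours post fertilization.
#' @param genotype Free-text genotype label.
#' @param n_embryos Cells are attributed round-robin to this many embryos.
#' @return A `vm_cohort_group` list.
#' @export
cohort_group <- function(name, vessel, population,
                         vessel_type = c("artery", "vein"),
                         region = c("trunk", "tail"),
                         stage_hpf = 72, genotype = "wt", n_embryos = 3) {
  vessel_type <- match.arg(vessel_type)
  region <- match.arg(region)
  structure(list(name = name, vessel = vessel, population = population,
                 vessel_type = vessel_type, region = region,
                 stage_hpf = stage_hpf, genotype = genotype,
                 n_embryos = n_embryos),
            class = "vm_cohort_group")
}

#' Generate a cohort of traced outlines across groups
#'
#' Runs [tessellate_cells()] and [sample_outline()] for each group with a
#' group-specific seed derived from `seed`, and attaches metadata.
#'
#' @param groups List of [cohort_group()]s (unique names).
#' @param n_points,noise_sd,jitter_spacing Passed to [sample_outline()].
#' @param seed Integer master seed.
#' @return A `vm_cohort` list with elements `outlines` (point table with
#'   metadata columns) and `ground_truth` (per-cell truth table).
#' @export
make_cohort <- function(groups, n_points = 100, noise_sd = 0.2, seed = 1L,
                        jitter_spacing = FALSE) {
  if (!length(groups)) vm_stop("at least one group is required")
  nm <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(nm)) vm_stop(sprintf("duplicate group name(s): %s",
                                         paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  outl <- list(); truth <- list()
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    pop <- g$population
    pop$seed <- derive_seed(seed, 2L * k)
    cells <- tessellate_cells(g$vessel, pop)
    pts <- sample_outline(cells, n_points = n_points, noise_sd = noise_sd,
                          seed = derive_seed(seed, 2L * k + 1L),
                          jitter_spacing = jitter_spacing)
    cells$cell_id <- paste(g$name, cells$cell_id, sep = "_")
    pts$cell_id <- paste(g$name, pts$cell_id, sep = "_")
    embryo <- sprintf("embryo%02d", ((seq_len(nrow(cells)) - 1L) %% g$n_embryos) + 1L)
    meta <- tibble::tibble(cell_id = cells$cell_id, group = g$name,
                           vessel = g$vessel_type, region = g$region,
                           stage_hpf = g$stage_hpf, genotype = g$genotype,
                           embryo_id = embryo)
    outl[[k]] <- dplyr::left_join(pts, meta, by = "cell_id")
    truth[[k]] <- dplyr::left_join(cells, meta, by = "cell_id")
  }
  structure(list(outlines = dplyr::bind_rows(outl),
                 ground_truth = dplyr::bind_rows(truth)),
            class = "vm_cohort")
}

#' @export
print.vm_cohort <- function(x, ...) {
  cat(sprintf("<vm_cohort> %d cells, %d points, %d group(s)\n",
              dplyr::n_distinct(x$outlines$cell_id), nrow(x$outlines),
              dplyr::n_distinct(x$outlines$group)))
  invisible(x)
}

#' Sample points on the vessel wall itself
#'
#' Dense surface sampling (a grid in axial position and cross-section
#' parameter) with optional tracing noise; used for diameter measurements
#' and for centerline checks independent of any cell tessellation.
#'
#' @param vessel A `vm_vessel` or [vessel_spec()] (length must be set).
#' @param n_axial,n_circ Grid resolution.
#' @param noise_sd Isotropic Gaussian noise s.d., µm.
#' @param seed Integer seed.
#' @return Tibble with columns `x_um`, `y_um`, `z_um`, `u`, `v`.
#' @export
sample_surface_points <- function(vessel, n_axial = 50, n_circ = 60,
                                  noise_sd = 0, seed = 1L) {
  if (inherits(vessel, "vm_vessel_spec")) vessel <- make_vessel(vessel)
  spec <- vessel$spec
  if (is.null(spec$length)) vm_stop("vessel length must be set to sample surface points")
  u <- seq(0, spec$length, length.out = n_axial)
  v <- if (spec$cross_section == "hyperbola_patch") {
    seq(spec$v_range[1], spec$v_range[2], length.out = n_circ)
  } else {
    seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  }
  grid <- expand.grid(u = u, v = v)
  p <- vessel$point(grid$u, grid$v)
  if (noise_sd > 0) {
    set.seed(seed)
    p <- p + matrix(rnorm(3 * nrow(p), 0, noise_sd), ncol = 3)
  }
  tibble::tibble(x_um = p[, 1], y_um = p[, 2], z_um = p[, 3],
                 u = grid$u, v = grid$v)
}
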