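# Centerline estimation, rigid alignment and unrolling.

cylinder_cloud <- function(n = 400, r = 8, len = 120, seed = 1) {
  set.seed(seed)
  u <- runif(n, 0, len)
  v <- runif(n, 0, 2 * pi)
  tibble::tibble(x_um = u, y_um = r * cos(v), z_um = r * sin(v))
}

# symmetric grid sampling: the principal axis is exactly the tube axis
cylinder_grid <- function(r = 8, len = 120) {
  sample_surface_points(vessel_spec(radius_y = r, length = len),
                        n_axial = 30, n_circ = 24)
}

test_that("centerline recovery finds the tube axis in any orientation", {
  pts <- cylinder_grid()
  fr <- estimate_centerline(pts)
  expect_lt(max(abs(fr$direction - c(1, 0, 0))), 1e-6)
  expect_lt(max(abs(fr$rotation %*% fr$direction - c(1, 0, 0))), 1e-9)
  expect_lt(max(abs(crossprod(fr$rotation) - diag(3))), 1e-9)
  expect_equal(det(fr$rotation), 1, tolerance = 1e-9)

  # rotate the same cylinder 90 degrees about z: axis becomes +y
  R <- rot3("z", pi / 2)
  P <- as.matrix(pts[, c("x_um", "y_um", "z_um")]) %*% t(R)
  fr2 <- estimate_centerline(tibble::tibble(x_um = P[, 1], y_um = P[, 2], z_um = P[, 3]))
  expect_lt(max(abs(fr2$direction - c(0, 1, 0))), 1e-6)

  expect_error(
    estimate_centerline(tibble::tibble(x_um = rep(1, 10), y_um = rep(2, 10),
                                       z_um = rep(3, 10))),
    "degenerate")
})

test_that("alignment is a rigid motion that preserves pairwise distances", {
  pts <- cylinder_cloud(n = 120)
  R <- rot3("y", 0.8) %*% rot3("z", -0.4)
  P <- as.matrix(pts) %*% t(R)
  moved <- tibble::tibble(x_um = P[, 1] + 30, y_um = P[, 2] - 12, z_um = P[, 3] + 5)
  fr <- estimate_centerline(moved)
  al <- align_outlines(moved, fr)
  d_before <- dist(as.matrix(moved))
  d_after <- dist(cbind(al$x_um, al$y_um, al$z_um))
  expect_lt(max(abs(d_before - d_after)), 1e-9)

  # identity frame leaves the input unchanged
  idf <- structure(list(origin = c(0, 0, 0), direction = c(1, 0, 0),
                        rotation = diag(3)), class = "vm_frame")
  expect_equal(align_outlines(pts, idf), pts, tolerance = 1e-15)

  # translation-only frame subtracts the origin
  trf <- structure(list(origin = c(1, 2, 3), direction = c(1, 0, 0),
                        rotation = diag(3)), class = "vm_frame")
  sh <- align_outlines(pts, trf)
  expect_equal(sh$x_um, pts$x_um - 1, tolerance = 1e-15)
  expect_equal(sh$z_um, pts$z_um - 3, tolerance = 1e-15)
})

# Rectangle drawn on a cylinder: the development is exactly (x, r*theta).
rect_on_cylinder <- function(r, theta_w, len, n_side = 25, theta0 = 0.3, x0 = 5) {
  tt <- seq(0, theta_w, length.out = n_side)
  xx <- seq(0, len, length.out = n_side)
  th <- c(tt, rep(theta_w, n_side), rev(tt), rep(0, n_side)) + theta0
  xs <- c(rep(0, n_side), xx, rep(len, n_side), rev(xx)) + x0
  tibble::tibble(cell_id = "rect", point_index = seq_along(th),
                 x_um = xs, y_um = r * cos(th), z_um = r * sin(th))
}

test_that("unrolling a cylinder reproduces the closed-form development", {
  r <- 5; theta_w <- 1; len <- 10
  pts <- rect_on_cylinder(r, theta_w, len)
  model <- fit_cross_section(pts, "ellipse")
  un <- unroll_outlines(pts, model)
  # developed rectangle: width r*theta, height len (area = 50 for these values)
  expect_equal(diff(range(un$s_um)), r * theta_w, tolerance = 1e-6)
  expect_equal(diff(range(un$x_um)), len, tolerance = 1e-12)
  expect_equal(polygon_area_oracle(un$x_um, un$s_um), r * theta_w * len,
               tolerance = 1e-6)
  # s equals r*theta up to the seam offset
  th <- atan2(pts$z_um, pts$y_um)
  expect_lt(max(abs((un$s_um - un$s_um[1]) - r * (th - th[1]))), 1e-6)
})

test_that("a small geodesic disc on a wide cylinder unrolls to a planar disc", {
  r <- 50
  t <- seq(0, 2 * pi, length.out = 201)[-201]
  # disc of radius 2 in the developed plane at (x0, s0)
  x <- 20 + 2 * cos(t)
  th <- (2 * sin(t)) / r + 0.5
  pts <- tibble::tibble(cell_id = "disc", point_index = seq_along(t),
                        x_um = x, y_um = r * cos(th), z_um = r * sin(th))
  # wall points around the full circumference to pin down the conic
  wall <- sample_surface_points(vessel_spec(radius_y = r, length = 40),
                                n_axial = 10, n_circ = 60)
  model <- fit_cross_section(wall, "ellipse")
  un <- unroll_outlines(pts, model)
  expect_equal(polygon_area_oracle(un$x_um, un$s_um), 4 * pi, tolerance = 0.005 * 4 * pi)
})

test_that("unrolled arc length matches the geodesic length of the 3D boundary", {
  co <- small_cohort(n_cells = 6, noise_sd = 0, seed = 3)
  un <- unroll_cohort(co$outlines, kind = "ellipse")
  per3d <- co$outlines |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(
      # chord length of the closed 3D polyline: a lower bound that converges
      # to the geodesic boundary length at 100 points per outline
      l3 = {
        P <- cbind(x_um, y_um, z_um)
        Q <- rbind(P[-1, ], P[1, ])
        sum(sqrt(rowSums((Q - P)^2)))
      }, .groups = "drop")
  per2d <- un |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(l2 = {
      P <- cbind(x_um, s_um); Q <- rbind(P[-1, ], P[1, ])
      sum(sqrt(rowSums((Q - P)^2)))
    }, .groups = "drop")
  m <- dplyr::inner_join(per3d, per2d, by = "cell_id")
  expect_lt(max(abs(m$l2 - m$l3) / m$l3), 0.01)
})

test_that("seam placement keeps s continuous along every outline", {
  co <- small_cohort(n_cells = 20, noise_sd = 0.2, seed = 8)
  un <- unroll_cohort(co$outlines, kind = "ellipse")
  models <- attr(un, "models")
  for (g in names(models)) {
    m <- models[[g]]
    total <- vesselmorph:::conic_arclength_fun(m, 0, 2 * pi)(2 * pi)
    jumps <- un |>
      dplyr::filter(group == g) |>
      dplyr::group_by(cell_id) |>
      dplyr::summarise(mx = max(abs(diff(s_um))), .groups = "drop")
    expect_lt(max(jumps$mx), total / 4)
  }
})

test_that("points off the wall and self-wrapping outlines are rejected", {
  r <- 5
  pts <- rect_on_cylinder(r, 1, 10)
  model <- fit_cross_section(pts, "ellipse")
  bad <- pts
  bad$y_um[3] <- bad$y_um[3] + 3 # 60% of the radius off the wall
  expect_error(unroll_outlines(bad, model), "radial tolerance")

  th <- seq(0, 2.4 * pi, length.out = 120)
  wrap <- tibble::tibble(cell_id = "w", point_index = seq_along(th),
                         x_um = seq(0, 10, length.out = 120),
                         y_um = r * cos(th), z_um = r * sin(th))
  expect_error(unroll_outlines(wrap, model), "wraps")
})

test_that("morphometrics are invariant under rigid motions of the raw data", {
  co <- small_cohort(n_cells = 10, noise_sd = 0, seed = 5)
  base <- compute_shapes(unroll_cohort(co$outlines, kind = "ellipse"))
  R <- rot3("x", 1.1) %*% rot3("y", -0.6)
  moved <- co$outlines
  P <- cbind(moved$x_um, moved$y_um, moved$z_um) %*% t(R)
  moved$x_um <- P[, 1] + 40; moved$y_um <- P[, 2] + 7; moved$z_um <- P[, 3] - 15
  alt <- compute_shapes(unroll_cohort(moved, kind = "ellipse"))
  m <- dplyr::inner_join(base, alt, by = "cell_id", suffix = c("", "_rot"))
  expect_lt(max(abs(m$area_um2 - m$area_um2_rot) / m$area_um2), 1e-6)
  expect_lt(max(abs(m$perimeter_um - m$perimeter_um_rot) / m$perimeter_um), 1e-6)
  expect_lt(max(abs(m$elongation - m$elongation_rot) / m$elongation), 1e-6)
  expect_lt(max(abs(m$angle_deg - m$angle_deg_rot)), 1e-4)
})

test_that("hyperbolic wall patches unroll without a seam", {
  vs <- vessel_spec("hyperbola_patch", radius_y = 6, radius_z = 4,
                    v_range = c(-1.2, 1.2))
  cells <- tessellate_cells(vs, population_spec(4, 120, seed = 2))
  pts <- sample_outline(cells, noise_sd = 0, seed = 1)
  model <- fit_cross_section(pts, "auto")
  expect_identical(model$kind, "hyperbola")
  un <- unroll_outlines(pts, model)
  sh <- compute_shapes(un)
  truth <- cells
  m <- dplyr::inner_join(sh, truth[, c("cell_id", "true_area")], by = "cell_id")
  expect_lt(max(abs(m$area_um2 - m$true_area) / m$true_area), 0.01)
})
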