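# Synthetic vessels, tessellation and outline sampling.

test_that("parametric surfaces honour their cross-section definition", {
  v <- make_vessel(vessel_spec("circle", radius_y = 5, length = 100))
  expect_equal(as.numeric(v$point(0, 0)), c(0, 5, 0), tolerance = 1e-12)

  ve <- make_vessel(vessel_spec("ellipse", radius_y = 8, radius_z = 4, length = 50))
  g <- expand.grid(u = seq(0, 50, length.out = 7), v = seq(0, 2 * pi, length.out = 33))
  p <- ve$point(g$u, g$v)
  expect_lt(max(abs((p[, 2] / 8)^2 + (p[, 3] / 4)^2 - 1)), 1e-9)

  vt <- make_vessel(vessel_spec("circle", radius_y = 5, length = 100, taper = 0.01))
  r_end <- sqrt(sum(vt$point(100, 0.7)[2:3]^2))
  r_start <- sqrt(sum(vt$point(0, 0.7)[2:3]^2))
  expect_equal(r_end / r_start, 2, tolerance = 1e-12)

  vh <- make_vessel(vessel_spec("hyperbola_patch", radius_y = 3, radius_z = 2, length = 40))
  ph <- vh$point(seq(0, 40, length.out = 20), seq(-1, 1, length.out = 20))
  expect_lt(max(abs((ph[, 2] / 3)^2 - (ph[, 3] / 2)^2 - 1)), 1e-9)
})

test_that("invalid vessel specs are rejected", {
  expect_error(vessel_spec(radius_y = -1), "positive")
  expect_error(vessel_spec(radius_y = 5, length = 0), "positive")
  expect_error(vessel_spec(radius_y = 5, axis_direction = c(0, 0, 0)), "non-zero")
})

test_that("tessellation places cells with exact developed-plane ground truth", {
  cells <- tessellate_cells(vessel_spec(radius_y = 12.5),
                            population_spec(100, 500, area_cv = 0.2, seed = 7))
  # lognormal generator: sample mean within 3 SEM of the requested mean
  sem <- 500 * 0.2 / sqrt(100)
  expect_lt(abs(mean(cells$true_area) - 500), 3 * sem)
  # ground truth equals the developed-plane ellipse area by construction
  expect_equal(cells$true_area, pi * cells$semi_major * cells$semi_minor,
               tolerance = 1e-12)
  expect_true(all(cells$true_elongation >= 1))
  expect_true(all(cells$true_angle >= 0 & cells$true_angle <= 90))
  # area conservation on the cylinder
  ves <- attr(cells, "vessel")
  expect_lte(sum(cells$true_area),
             2 * pi * ves$spec$radius_y * ves$spec$length)
})

test_that("tessellation is deterministic and rejects overcrowding", {
  spec <- vessel_spec(radius_y = 12.5)
  pop <- population_spec(40, 450, seed = 3)
  a <- tessellate_cells(spec, pop)
  b <- tessellate_cells(spec, pop)
  expect_identical(a$true_area, b$true_area)
  expect_identical(a$u_center, b$u_center)
  # fixed short vessel cannot hold the population
  expect_error(
    tessellate_cells(vessel_spec(radius_y = 12.5, length = 30),
                     population_spec(40, 450, seed = 3)),
    "achievable maximum")
  # a huge cell cannot fit around a thin tube at all
  expect_error(
    tessellate_cells(vessel_spec(radius_y = 2), population_spec(5, 2000, seed = 1)),
    "overcrowded")
  # tapered tubes are not isometric: refuse to tessellate
  expect_error(
    tessellate_cells(vessel_spec(radius_y = 10, length = 200, taper = 0.001),
                     population_spec(5, 100, seed = 1)),
    "untapered")
})

test_that("noiseless outlines lie exactly on the tube surface and boundary", {
  cells <- tessellate_cells(vessel_spec(radius_y = 10),
                            population_spec(6, 300, seed = 5))
  pts <- sample_outline(cells, n_points = 100, noise_sd = 0, seed = 1)
  expect_identical(nrow(pts), 600L)
  r <- sqrt(pts$y_um^2 + pts$z_um^2)
  expect_lt(max(abs(r - 10)), 1e-9)
  # developed coordinates satisfy each cell's boundary-ellipse equation
  for (i in seq_len(nrow(cells))) {
    row <- cells[i, ]
    p <- pts[pts$cell_id == row$cell_id, ]
    u <- p$x_um - row$u_center
    s <- 10 * atan2(p$z_um, p$y_um)
    s <- s + round((row$s_center - s) / (2 * pi * 10)) * 2 * pi * 10 - row$s_center
    co <- cos(row$orientation_rad); si <- sin(row$orientation_rad)
    ex <- co * u + si * s; ey <- -si * u + co * s
    expect_lt(max(abs((ex / row$semi_major)^2 + (ey / row$semi_minor)^2 - 1)), 1e-9)
  }
})

test_that("tracing noise has the configured magnitude", {
  cells <- tessellate_cells(vessel_spec(radius_y = 10),
                            population_spec(10, 300, seed = 5))
  noisy <- sample_outline(cells, n_points = 100, noise_sd = 0.2, seed = 9)
  clean <- sample_outline(cells, n_points = 100, noise_sd = 0, seed = 9)
  # RMS distance to the true boundary curve is bounded by the full 3-D
  # offset RMS (sd * sqrt(3)) and is at least the transverse component
  d <- sqrt((noisy$x_um - clean$x_um)^2 + (noisy$y_um - clean$y_um)^2 +
              (noisy$z_um - clean$z_um)^2)
  expect_gt(sqrt(mean(d^2)), 0.1)
  expect_lt(sqrt(mean(d^2)), 0.2 * sqrt(3) * 1.15)
  expect_error(sample_outline(cells, n_points = 4), ">= 8")
})

test_that("cohorts honour group effect multipliers and reject duplicates", {
  co <- make_cohort(list(
    cohort_group("ref", vessel_spec(radius_y = 14),
                 population_spec(200, 350, seed = 1), "vein", "tail"),
    cohort_group("mut", vessel_spec(radius_y = 14),
                 population_spec(200, 350, seed = 2, area_effect_multiplier = 1.5),
                 "vein", "tail", genotype = "mutant")),
    noise_sd = 0, seed = 1)
  tr <- co$ground_truth
  m_ref <- mean(tr$true_area[tr$group == "ref"])
  m_mut <- mean(tr$true_area[tr$group == "mut"])
  expect_gt(m_mut / m_ref, 1.4)
  expect_lt(m_mut / m_ref, 1.6)

  one <- make_cohort(list(
    cohort_group("only", vessel_spec(radius_y = 12),
                 population_spec(17, 300, seed = 1))), seed = 2)
  expect_identical(dplyr::n_distinct(one$outlines$cell_id), 17L)

  expect_error(make_cohort(list(
    cohort_group("a", vessel_spec(radius_y = 12), population_spec(5, 300, seed = 1)),
    cohort_group("a", vessel_spec(radius_y = 12), population_spec(5, 300, seed = 2))),
    seed = 1), "duplicate")
})

test_that("cohort generation is bitwise deterministic for a fixed seed", {
  a <- small_cohort(n_cells = 8, seed = 4)
  b <- small_cohort(n_cells = 8, seed = 4)
  expect_identical(a$outlines, b$outlines)
  expect_identical(a$ground_truth$true_area, b$ground_truth$true_area)
})
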