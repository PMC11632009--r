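# Shared fixtures and independent oracles for the test suite.

# Points on an ellipse from its generating parameters (the oracle for
# conic-fit recovery: fit results are compared to these inputs).
ellipse_points <- function(n, a, b, cx = 0, cy = 0, tilt = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ct <- cos(tilt); st <- sin(tilt)
  ex <- a * cos(t); ey <- b * sin(t)
  cbind(x = cx + ct * ex - st * ey, y = cy + st * ex + ct * ey)
}

# Rotation matrix about a coordinate axis, for rigid-motion tests.
rot3 <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c <- cos(angle); s <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3),
    y = matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3),
    z = matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3))
}

# A small standard cohort: one artery-like and one vein-like tube.
small_cohort <- function(n_cells = 25, noise_sd = 0.2, seed = 11,
                         multiplier_b = 1) {
  make_cohort(list(
    cohort_group("ga", vessel_spec(radius_y = 12.5),
                 population_spec(n_cells, 450, seed = 1),
                 "artery", "trunk"),
    cohort_group("gb", vessel_spec(radius_y = 17.5),
                 population_spec(n_cells, 300, seed = 2,
                                 area_effect_multiplier = multiplier_b),
                 "vein", "trunk")),
    noise_sd = noise_sd, seed = seed)
}

# Brute-force Gaussian KDE with Scott's rule: explicit per-point loop using
# solve()/det() — an independent path from the package's Cholesky-based
# vectorized evaluator.
bf_kde_density <- function(train, at) {
  n <- nrow(train); d <- ncol(train)
  H <- stats::cov(train) * n^(-2 / (d + 4))
  Hi <- solve(H)
  nc <- sqrt((2 * pi)^d * det(H))
  apply(at, 1, function(x) {
    mean(exp(-0.5 * apply(train, 1, function(y) {
      v <- x - y
      as.numeric(t(v) %*% Hi %*% v)
    }))) / nc
  })
}

# Discrete JSD (base 2) from two density vectors, written as the plain
# textbook sum.
bf_discrete_jsd <- function(pa, pb) {
  p <- pa / sum(pa); q <- pb / sum(pb)
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log2(q[i] / m[i])
  }
  s
}

# Independent plain-loop shoelace area, for cross-checking developed areas.
polygon_area_oracle <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# Mean silhouette width of a 2-D embedding under given labels.
silhouette_mean <- function(xy, labels) {
  D <- as.matrix(stats::dist(xy))
  n <- nrow(xy)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(l) mean(D[i, labels == l]),
                    numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
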