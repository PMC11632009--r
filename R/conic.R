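# Direct least-squares conic fitting and conic geometry.
#
# Coefficients are stored as c(A, B, C, D, E, F) for
#   A x^2 + B xy + C y^2 + D x + E y + F = 0.
# Two fitters are provided: the ellipse-specific direct fit
# (Halir & Flusser's numerically stable formulation of Fitzgibbon's
# 4AC - B^2 = 1 constraint), and an unconstrained algebraic fit via the
# smallest right singular vector, used for hyperbolae and for kind
# auto-detection. Both operate on centred/scaled coordinates and map the
# coefficients back, which keeps the normal matrices well conditioned at
# micrometre magnitudes.

conic_normalize_points <- function(x, y) {
  cx <- mean(x); cy <- mean(y)
  s <- mean(sqrt((x - cx)^2 + (y - cy)^2))
  if (s <= 0) s <- 1
  list(u = (x - cx) / s, v = (y - cy) / s, cx = cx, cy = cy, s = s)
}

# Map coefficients fitted in u = (x-cx)/s, v = (y-cy)/s back to raw x, y.
conic_denormalize <- function(k, cx, cy, s) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  out <- c(
    A / s^2,
    B / s^2,
    C / s^2,
    (-2 * A * cx - B * cy) / s^2 + D / s,
    (-B * cx - 2 * C * cy) / s^2 + E / s,
    (A * cx^2 + B * cx * cy + C * cy^2) / s^2 - (D * cx + E * cy) / s + F
  )
  out / sqrt(sum(out^2))
}

# Ellipse-constrained direct least squares (Halir & Flusser).
fit_conic_ellipse <- function(x, y) {
  np <- conic_normalize_points(x, y)
  u <- np$u; v <- np$v
  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T3)) vm_stop("conic fit failed: degenerate point configuration (collinear points?)")
  M <- S1 + S2 %*% T3
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  # keep the real eigenvector satisfying the ellipse constraint 4AC - B^2 > 0
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  idx <- which(cond > 0)
  if (!length(idx)) vm_stop("ellipse fit failed: no eigenvector satisfies the ellipse constraint")
  a1 <- vecs[, idx[1]]
  k <- c(a1, as.vector(T3 %*% a1))
  conic_denormalize(k, np$cx, np$cy, np$s)
}

# Unconstrained algebraic conic fit: smallest right singular vector of the
# design matrix. Exact for noiseless conic data; used for hyperbolae and
# for discriminant-based kind selection.
fit_conic_general <- function(x, y) {
  np <- conic_normalize_points(x, y)
  u <- np$u; v <- np$v
  Z <- cbind(u^2, u * v, v^2, u, v, 1)
  sv <- svd(Z)
  k <- sv$v[, 6]
  conic_denormalize(k, np$cx, np$cy, np$s)
}

conic_discriminant <- function(coef) coef[2]^2 - 4 * coef[1] * coef[3]

# Geometric parameters (center, semi-axes, tilt) from general coefficients.
# For an ellipse, semi_axes = (alpha along tilt, beta perpendicular).
# For a hyperbola, alpha is the transverse semi-axis and tilt points along
# the transverse axis.
conic_parameters <- function(coef) {
  A <- coef[1]; B <- coef[2]; C <- coef[3]; D <- coef[4]; E <- coef[5]; F <- coef[6]
  disc <- conic_discriminant(coef)
  if (abs(disc) < 1e-9 * (A^2 + B^2 + C^2)) {
    vm_stop("degenerate conic: discriminant at the parabolic boundary; cannot classify as ellipse or hyperbola")
  }
  M <- matrix(c(2 * A, B, B, 2 * C), 2, 2)
  ctr <- tryCatch(solve(M, c(-D, -E)), error = function(e) NULL)
  if (is.null(ctr)) vm_stop("degenerate conic: no finite center")
  theta <- 0.5 * atan2(B, A - C)
  ct <- cos(theta); st <- sin(theta)
  Ap <- A * ct^2 + B * ct * st + C * st^2
  Cp <- A * st^2 - B * ct * st + C * ct^2
  F0 <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 + D * ctr[1] + E * ctr[2] + F
  p <- -F0 / Ap
  q <- -F0 / Cp
  if (p > 0 && q > 0) {
    kind <- "ellipse"
    alpha <- sqrt(p); beta <- sqrt(q)
  } else if (p > 0 && q < 0) {
    kind <- "hyperbola"
    alpha <- sqrt(p); beta <- sqrt(-q)
  } else if (p < 0 && q > 0) {
    kind <- "hyperbola"
    alpha <- sqrt(q); beta <- sqrt(-p)
    theta <- theta + pi / 2
  } else {
    vm_stop("degenerate conic: empty locus (both squared terms negative)")
  }
  # canonical tilt in (-pi/2, pi/2]
  theta <- atan2(sin(theta), cos(theta))
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  list(kind = kind, center = as.numeric(ctr), semi_axes = c(alpha, beta), tilt = theta)
}

# Sampson (first-order orthogonal) distance of points to the conic.
conic_sampson <- function(coef, x, y) {
  A <- coef[1]; B <- coef[2]; C <- coef[3]; D <- coef[4]; E <- coef[5]; F <- coef[6]
  Q <- A * x^2 + B * x * y + C * y^2 + D * x + E * y + F
  gx <- 2 * A * x + B * y + D
  gy <- B * x + 2 * C * y + E
  abs(Q) / pmax(sqrt(gx^2 + gy^2), .Machine$double.eps)
}

# --- parametric geometry on a fitted conic -------------------------------

# Point on the conic at parameter t, in the raw (y, z) plane.
# ellipse: center + R(tilt) %*% (alpha cos t, beta sin t)
# hyperbola: one branch, center + R(tilt) %*% (branch * alpha cosh t, beta sinh t)
conic_point <- function(par, t, branch = 1) {
  ct <- cos(par$tilt); st <- sin(par$tilt)
  if (par$kind == "ellipse") {
    px <- par$semi_axes[1] * cos(t)
    py <- par$semi_axes[2] * sin(t)
  } else {
    px <- branch * par$semi_axes[1] * cosh(t)
    py <- par$semi_axes[2] * sinh(t)
  }
  cbind(par$center[1] + ct * px - st * py,
        par$center[2] + st * px + ct * py)
}

conic_speed <- function(par, t) {
  if (par$kind == "ellipse") {
    sqrt(par$semi_axes[1]^2 * sin(t)^2 + par$semi_axes[2]^2 * cos(t)^2)
  } else {
    sqrt(par$semi_axes[1]^2 * sinh(t)^2 + par$semi_axes[2]^2 * cosh(t)^2)
  }
}

# Cumulative arc length S(t) from t0, as a monotone spline over a fine grid.
# Composite Simpson on 2^13 intervals puts the quadrature error many orders
# below tracing noise (relative error ~ (dt)^4 ~ 1e-12 on a full ellipse).
conic_arclength_fun <- function(par, t_min, t_max, n_grid = 8192) {
  tg <- seq(t_min, t_max, length.out = n_grid + 1)
  h <- (t_max - t_min) / n_grid
  f <- conic_speed(par, tg)
  mid <- conic_speed(par, (tg[-1] + tg[-length(tg)]) / 2)
  seg <- h / 6 * (f[-length(f)] + 4 * mid + f[-1])
  S <- c(0, cumsum(seg))
  splinefun(tg, S, method = "hyman")
}

# Nearest-point projection of (y, z) points onto the conic: coarse grid over
# the parameter, then golden-section refinement around the best cell.
# Returns the parameter t, the projection distance, and for hyperbolae the
# branch sign.
conic_project <- function(par, y, z, n_grid = 720) {
  n <- length(y)
  if (par$kind == "ellipse") {
    tg <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
    P <- conic_point(par, tg)
    t_out <- numeric(n); d_out <- numeric(n)
    step <- 2 * pi / n_grid
    for (i in seq_len(n)) {
      d2 <- (P[, 1] - y[i])^2 + (P[, 2] - z[i])^2
      j <- which.min(d2)
      f <- function(t) {
        p <- conic_point(par, t)
        (p[1] - y[i])^2 + (p[2] - z[i])^2
      }
      opt <- optimize(f, interval = c(tg[j] - step, tg[j] + step), tol = 1e-12)
      t_out[i] <- opt$minimum
      d_out[i] <- sqrt(opt$objective)
    }
    list(t = t_out, dist = d_out, branch = rep(1, n))
  } else {
    ct <- cos(par$tilt); st <- sin(par$tilt)
    # work in the conic frame; branch chosen by the sign along the transverse axis
    u <- ct * (y - par$center[1]) + st * (z - par$center[2])
    w <- -st * (y - par$center[1]) + ct * (z - par$center[2])
    br <- ifelse(u >= 0, 1, -1)
    t_max <- max(asinh(abs(w) / par$semi_axes[2]), asinh(3)) + 1
    tg <- seq(-t_max, t_max, length.out = n_grid + 1)
    step <- 2 * t_max / n_grid
    t_out <- numeric(n); d_out <- numeric(n)
    for (i in seq_len(n)) {
      pu <- br[i] * par$semi_axes[1] * cosh(tg)
      pw <- par$semi_axes[2] * sinh(tg)
      d2 <- (pu - u[i])^2 + (pw - w[i])^2
      j <- which.min(d2)
      f <- function(t) {
        (br[i] * par$semi_axes[1] * cosh(t) - u[i])^2 +
          (par$semi_axes[2] * sinh(t) - w[i])^2
      }
      opt <- optimize(f, interval = c(tg[j] - step, tg[j] + step), tol = 1e-12)
      t_out[i] <- opt$minimum
      d_out[i] <- sqrt(opt$objective)
    }
    list(t = t_out, dist = d_out, branch = br)
  }
}
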