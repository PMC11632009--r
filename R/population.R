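# Population-level comparison of cell shapes: feature normalization, UMAP
# embedding with per-group covariance ellipses, and Jensen-Shannon
# divergence between 4D shape distributions estimated by Gaussian KDE.

#' Fixed order of the four shape features
#'
#' Area, angle of alignment, elongation, perimeter — the feature order used
#' by every population-level function in the package.
#' @export
vm_feature_cols <- c("area_um2", "angle_deg", "elongation", "perimeter_um")

#' Z-score the shape features
#'
#' Centers and scales each feature column to mean 0, s.d. 1. The scaling
#' parameters are stored in attributes `"feature_center"` and
#' `"feature_scale"` for inverse mapping.
#'
#' @param shapes Shape table from [compute_shapes()] (or any tibble with the
#'   feature columns).
#' @param features Feature columns (default [vm_feature_cols]).
#' @return The table with features z-scored.
#' @export
normalize_features <- function(shapes, features = vm_feature_cols) {
  check_columns(shapes, features, "shape table")
  if (nrow(shapes) < 2) vm_stop("need at least 2 records to normalize")
  ctr <- vapply(shapes[features], mean, numeric(1))
  scl <- vapply(shapes[features], sd, numeric(1))
  zero <- features[scl == 0 | !is.finite(scl)]
  if (length(zero)) {
    vm_stop(sprintf("zero-variance feature(s): %s; cannot z-score",
                    paste(zero, collapse = ", ")))
  }
  out <- shapes
  for (f in features) out[[f]] <- (out[[f]] - ctr[[f]]) / scl[[f]]
  attr(out, "feature_center") <- ctr
  attr(out, "feature_scale") <- scl
  out
}

# --- Gaussian kernel density estimation ----------------------------------

# Scott's-rule Gaussian KDE: bandwidth matrix H = cov(X) * n^(-2/(d+4)).
# Returns log-space-safe densities of `at` under the KDE of `train`.
gauss_kde_density <- function(train, at) {
  n <- nrow(train); d <- ncol(train)
  H <- cov(train) * n^(-2 / (d + 4))
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) {
    vm_stop("singular covariance in a group (duplicated points or n <= number of features?); add jitter or more cells")
  }
  # Mahalanobis distances via the Cholesky factor of H
  A <- at %*% backsolve(R, diag(d))
  B <- train %*% backsolve(R, diag(d))
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  D2 <- outer(a2, b2, `+`) - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  norm_const <- (2 * pi)^(d / 2) * prod(diag(R))
  rowMeans(exp(-0.5 * D2)) / norm_const
}

#' Jensen-Shannon divergence between two samples via Gaussian KDE
#'
#' Fits one Scott's-rule Gaussian KDE per group, evaluates both densities on
#' the pooled sample points of the two groups, renormalizes the two density
#' vectors to discrete distributions and computes the discrete JSD with the
#' given log base (base 2 keeps the value in \[0, 1\]). The construction is
#' exactly symmetric and gives exactly 0 for a group against a copy of
#' itself. The square root of the JSD is the Jensen-Shannon distance.
#'
#' @param a,b Numeric matrices (rows = observations, same column count).
#' @param normalize Pool-z-score the features across both groups before the
#'   KDE (default `TRUE`). Per-group scaling would erase the very mean and
#'   scale differences the divergence is meant to measure.
#' @param log_base Base of the logarithm (default 2).
#' @return A `vm_jsd`: `jsd`, `js_distance`, `estimator` settings.
#' @export
kde_jsd <- function(a, b, normalize = TRUE, log_base = 2) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) vm_stop("groups must have the same number of features")
  d <- ncol(a)
  if (nrow(a) < 5 || nrow(b) < 5) {
    vm_stop("each group needs at least 5 observations for the KDE")
  }
  if (normalize) {
    pooled <- rbind(a, b)
    ctr <- colMeans(pooled)
    scl <- apply(pooled, 2, sd)
    if (any(scl == 0)) vm_stop("zero pooled variance in a feature; cannot normalize")
    a <- sweep(sweep(a, 2, ctr), 2, scl, `/`)
    b <- sweep(sweep(b, 2, ctr), 2, scl, `/`)
  }
  eval_pts <- rbind(a, b)
  pa <- gauss_kde_density(a, eval_pts)
  pb <- gauss_kde_density(b, eval_pts)
  p <- pa / sum(pa)
  q <- pb / sum(pb)
  m <- (p + q) / 2
  kl <- function(p, m) {
    i <- p > 0
    sum(p[i] * (log(p[i] / m[i]) / log(log_base)))
  }
  jsd <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  jsd <- min(max(jsd, 0), 1)
  structure(
    list(jsd = jsd, js_distance = sqrt(jsd),
         estimator = list(bandwidth_rule = "scott", n_eval = nrow(eval_pts),
                          log_base = log_base, normalized = normalize,
                          n_a = nrow(a), n_b = nrow(b), d = d)),
    class = "vm_jsd")
}

#' @export
print.vm_jsd <- function(x, ...) {
  lbl <- if (!is.null(x$group_a)) sprintf(" %s vs %s:", x$group_a, x$group_b) else ""
  cat(sprintf("<vm_jsd>%s JSD = %.4f (JS distance %.4f; base-%g KDE estimator, n = %d + %d)\n",
              lbl, x$jsd, x$js_distance, x$estimator$log_base,
              x$estimator$n_a, x$estimator$n_b))
  invisible(x)
}

shape_feature_matrix <- function(shapes, features) {
  check_columns(shapes, features, "shape table")
  as.matrix(shapes[features])
}

#' Jensen-Shannon divergence between two groups of a shape table
#'
#' @param shapes Shape table with a grouping column.
#' @param group_a,group_b Group labels to compare.
#' @param group_col Name of the grouping column (default `"group"`).
#' @param features Feature columns (default [vm_feature_cols], the original
#'   4D shape space).
#' @inheritParams kde_jsd
#' @return A `vm_jsd` with group labels attached.
#' @export
shape_jsd <- function(shapes, group_a, group_b, group_col = "group",
                      features = vm_feature_cols, normalize = TRUE,
                      log_base = 2) {
  check_columns(shapes, group_col, "shape table")
  g <- shapes[[group_col]]
  missing <- setdiff(c(group_a, group_b), unique(g))
  if (length(missing)) {
    vm_stop(sprintf("unknown group label(s): %s", paste(missing, collapse = ", ")))
  }
  res <- kde_jsd(shape_feature_matrix(shapes[g == group_a, ], features),
                 shape_feature_matrix(shapes[g == group_b, ], features),
                 normalize = normalize, log_base = log_base)
  res$group_a <- group_a
  res$group_b <- group_b
  res
}

#' All pairwise Jensen-Shannon divergences between groups
#'
#' @inheritParams shape_jsd
#' @param groups Which groups to include (default: all, in order of
#'   appearance).
#' @return A `vm_jsd_matrix`: symmetric matrix with zero diagonal plus the
#'   long table of pair results; `tidy()` returns the long table.
#' @export
pairwise_shape_jsd <- function(shapes, group_col = "group", groups = NULL,
                               features = vm_feature_cols, normalize = TRUE,
                               log_base = 2) {
  check_columns(shapes, group_col, "shape table")
  all_groups <- unique(shapes[[group_col]])
  if (is.null(groups)) groups <- all_groups
  missing <- setdiff(groups, all_groups)
  if (length(missing)) {
    vm_stop(sprintf("unknown group label(s): %s", paste(missing, collapse = ", ")))
  }
  if (length(groups) < 2) vm_stop("need at least 2 groups")
  k <- length(groups)
  M <- matrix(0, k, k, dimnames = list(groups, groups))
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- shape_jsd(shapes, groups[i], groups[j], group_col, features,
                     normalize, log_base)
      M[i, j] <- M[j, i] <- r$jsd
      rows[[length(rows) + 1]] <-
        tibble::tibble(group_a = groups[i], group_b = groups[j],
                       jsd = r$jsd, js_distance = r$js_distance)
    }
  }
  structure(list(matrix = M, pairs = dplyr::bind_rows(rows)),
            class = "vm_jsd_matrix")
}

#' @export
print.vm_jsd_matrix <- function(x, ...) {
  cat("<vm_jsd_matrix>\n")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Permutation test of a between-group Jensen-Shannon divergence
#'
#' Compares the observed KDE-JSD of two groups against the null distribution
#' obtained by shuffling group labels over the pooled records.
#'
#' @inheritParams shape_jsd
#' @param n_perm Number of permutations (default 99).
#' @param seed Integer seed for the permutations.
#' @return Tibble with `jsd_observed`, `p_value`, `n_perm`.
#' @export
jsd_permutation_test <- function(shapes, group_a, group_b, group_col = "group",
                                 features = vm_feature_cols, n_perm = 99,
                                 seed = 1L, normalize = TRUE, log_base = 2) {
  g <- shapes[[group_col]]
  A <- shape_feature_matrix(shapes[g == group_a, ], features)
  B <- shape_feature_matrix(shapes[g == group_b, ], features)
  obs <- kde_jsd(A, B, normalize, log_base)$jsd
  pooled <- rbind(A, B)
  na <- nrow(A)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nrow(pooled))
    kde_jsd(pooled[idx[seq_len(na)], , drop = FALSE],
            pooled[idx[-seq_len(na)], , drop = FALSE],
            normalize, log_base)$jsd
  }, numeric(1))
  tibble::tibble(group_a = group_a, group_b = group_b, jsd_observed = obs,
                 p_value = (1 + sum(null >= obs)) / (n_perm + 1),
                 n_perm = n_perm)
}

# --- UMAP embedding -------------------------------------------------------

#' Covariance bounding ellipse of a 2D point group
#'
#' The ellipse outlining the main part of a scatter: centered on the group
#' mean, axes from the eigendecomposition of the 2D covariance, scaled by
#' the chi-square quantile so it covers approximately `mass_fraction` of the
#' points when they are roughly Gaussian.
#'
#' @param xy Two-column matrix/data frame of coordinates (>= 3 non-collinear
#'   points).
#' @param mass_fraction Target coverage (default 0.90).
#' @return List with `center`, `semi_axes` (major, minor), `tilt` (radians),
#'   `mass_fraction`.
#' @export
bounding_ellipse <- function(xy, mass_fraction = 0.90) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) vm_stop("need at least 3 points for a bounding ellipse")
  V <- cov(xy)
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) <= 1e-12 * max(ev$values, 1)) {
    vm_stop("cannot fit a bounding ellipse to (nearly) collinear points")
  }
  r <- sqrt(qchisq(mass_fraction, df = 2))
  list(center = colMeans(xy),
       semi_axes = r * sqrt(ev$values),
       tilt = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
       mass_fraction = mass_fraction)
}

#' Embed shape parameters in 2D with UMAP
#'
#' Z-scores the four shape features, runs UMAP (exact nearest neighbours,
#' single-threaded layout, seeded — coordinates are bitwise reproducible for
#' a fixed seed and settings) and fits a covariance bounding ellipse to each
#' group's embedded points.
#'
#' @param shapes Shape table with a grouping column.
#' @param group_col Grouping column name (default `"group"`).
#' @param features Feature columns (default [vm_feature_cols]).
#' @param n_neighbors,min_dist,metric UMAP settings (defaults 15, 0.1,
#'   euclidean).
#' @param seed Integer seed (required for reproducibility).
#' @param mass_fraction Coverage of the per-group bounding ellipses.
#' @return A `vm_embedding`: `coords` (cell_id, umap1, umap2, group),
#'   `ellipses` (per-group tibble), `settings`.
#' @export
embed_shapes <- function(shapes, group_col = "group",
                         features = vm_feature_cols,
                         n_neighbors = 15, min_dist = 0.1,
                         metric = "euclidean", seed = 42L,
                         mass_fraction = 0.90) {
  check_columns(shapes, c(group_col, features), "shape table")
  n <- nrow(shapes)
  if (n < n_neighbors + 1) {
    vm_stop(sprintf("n = %d records is too small for n_neighbors = %d; use n_neighbors <= %d",
                    n, n_neighbors, n - 1))
  }
  X <- scale(shape_feature_matrix(shapes, features))
  set.seed(seed)
  emb <- uwot::umap(X, n_neighbors = n_neighbors, min_dist = min_dist,
                    metric = metric, nn_method = "fnn",
                    n_threads = 1, n_sgd_threads = 0)
  coords <- tibble::tibble(
    cell_id = if ("cell_id" %in% names(shapes)) shapes$cell_id else as.character(seq_len(n)),
    umap1 = emb[, 1], umap2 = emb[, 2],
    group = shapes[[group_col]])
  ell <- coords |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      e <- bounding_ellipse(cbind(df$umap1, df$umap2), mass_fraction)
      tibble::tibble(center_1 = e$center[1], center_2 = e$center[2],
                     semi_major = e$semi_axes[1], semi_minor = e$semi_axes[2],
                     tilt_rad = e$tilt, mass_fraction = e$mass_fraction)
    }) |>
    dplyr::ungroup()
  structure(
    list(coords = coords, ellipses = ell,
         settings = list(n_neighbors = n_neighbors, min_dist = min_dist,
                         metric = metric, seed = seed,
                         mass_fraction = mass_fraction)),
    class = "vm_embedding")
}

#' @export
print.vm_embedding <- function(x, ...) {
  cat(sprintf("<vm_embedding> %d cells, %d group(s); UMAP(n_neighbors = %d, min_dist = %g, seed = %d)\n",
              nrow(x$coords), dplyr::n_distinct(x$coords$group),
              x$settings$n_neighbors, x$settings$min_dist, x$settings$seed))
  invisible(x)
}
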