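# Alignment and unrolling of traced 3D outlines.
#
# The measurement chain is: estimate the vessel centerline from pooled
# outline points, rigidly move the vessel onto the x-axis, fit a conic
# (ellipse or hyperbola) to the transverse (y, z) cloud, then replace each
# point's (y, z) by the signed arc length along the conic to its
# nearest-point projection. With the untouched axial coordinate this
# flattens the tube wall into a 2D plane where planar morphometrics apply.

#' Estimate a vessel centerline frame from pooled outline points
#'
#' The axis direction is the principal (largest-variance) direction of the
#' pooled points, sign-fixed toward the +x hemisphere; the origin is the
#' centroid. The returned frame carries a rotation that maps the axis onto
#' +x.
#'
#' When outlines cover the tube asymmetrically (few cells), the raw
#' principal axis is biased; with `refine = TRUE` (default) the direction is
#' polished by minimizing the transverse conic-fit residual over small
#' rotations — the axis of a tube is the direction in which its wall
#' projects to the thinnest conic annulus.
#'
#' @param points Tibble with columns `x_um`, `y_um`, `z_um` (all outlines of
#'   one vessel segment pooled).
#' @param refine Polish the principal axis against the conic-fit residual.
#' @return A `vm_frame`: list with `origin`, `direction`, `rotation`
#'   (3x3, rows orthonormal, det +1, `rotation %*% direction == c(1,0,0)`).
#' @export
estimate_centerline <- function(points, refine = TRUE) {
  check_columns(points, c("x_um", "y_um", "z_um"), "outline table")
  P <- cbind(points$x_um, points$y_um, points$z_um)
  if (nrow(P) < 3) vm_stop("need at least 3 points to estimate a centerline")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc, nu = 0)
  span <- diff(range(Pc %*% sv$v[, 1]))
  if (!is.finite(span) || span <= 1) {
    vm_stop("degenerate point cloud: points span <= 1 µm along every direction; cannot estimate a centerline")
  }
  d <- sv$v[, 1]
  if (refine && nrow(Pc) >= 8) d <- refine_axis(Pc, d)
  # sign fix toward the +x hemisphere (then +y, +z on ties)
  key <- c(d[1], d[2], d[3])
  first <- which(abs(key) > 1e-12)[1]
  if (length(first) && key[first] < 0) d <- -d
  Fm <- axis_frame(d) # columns: d, e2, e3
  R <- t(Fm)          # rows: d, e2, e3 -> maps d to e1, det +1
  structure(list(origin = ctr, direction = d, rotation = R), class = "vm_frame")
}

# Polish an axis direction by minimizing the RMS Sampson residual of the
# algebraic conic fitted to the points projected along the axis. Exact for
# noiseless generalized cylinders; corrects the principal-axis bias on
# sparse, asymmetric outline coverage.
refine_axis <- function(Pc, d0) {
  F0 <- axis_frame(d0)
  obj <- function(ab) {
    d <- F0 %*% c(1, ab)
    d <- d / sqrt(sum(d^2))
    Fr <- axis_frame(as.numeric(d))
    y <- Pc %*% Fr[, 2]
    z <- Pc %*% Fr[, 3]
    coef <- tryCatch(fit_conic_general(as.numeric(y), as.numeric(z)),
                     error = function(e) NULL)
    if (is.null(coef)) return(Inf)
    mean(conic_sampson(coef, as.numeric(y), as.numeric(z))^2)
  }
  opt <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 400))
  d <- F0 %*% c(1, opt$par)
  as.numeric(d / sqrt(sum(d^2)))
}

#' Rigidly align outlines to a centerline frame
#'
#' Applies `rotation %*% (p - origin)` to every point: a rigid motion that
#' puts the vessel axis on the x-axis. All pairwise distances are preserved.
#'
#' @param points Outline tibble with `x_um`, `y_um`, `z_um`.
#' @param frame A `vm_frame` from [estimate_centerline()], or `NULL` to
#'   estimate it from `points`.
#' @return The same tibble with transformed coordinates.
#' @export
align_outlines <- function(points, frame = NULL) {
  check_columns(points, c("x_um", "y_um", "z_um"), "outline table")
  if (is.null(frame)) frame <- estimate_centerline(points)
  if (!inherits(frame, "vm_frame")) vm_stop("`frame` must be a vm_frame")
  P <- cbind(points$x_um, points$y_um, points$z_um)
  Q <- sweep(P, 2, frame$origin) %*% t(frame$rotation)
  out <- points
  out$x_um <- Q[, 1]; out$y_um <- Q[, 2]; out$z_um <- Q[, 3]
  out
}

#' Fit the vessel cross-section conic
#'
#' Direct least-squares conic fit to the transverse (y, z) coordinates of
#' aligned points. `kind = "ellipse"` uses the ellipse-constrained direct
#' fit; `"hyperbola"` the unconstrained algebraic fit (checked to be a
#' hyperbola); `"auto"` selects by the sign of the fitted conic discriminant
#' and refits ellipses with the constrained method.
#'
#' @param points Aligned tibble with `y_um`, `z_um`.
#' @param kind `"auto"`, `"ellipse"` or `"hyperbola"`.
#' @return A `vm_conic`: `kind`, `center` (y0, z0), `semi_axes` (alpha,
#'   beta), `tilt` (radians), `fit_rms` (µm, Sampson residual), `coef`,
#'   `n_points`.
#' @export
fit_cross_section <- function(points, kind = c("auto", "ellipse", "hyperbola")) {
  kind <- match.arg(kind)
  check_columns(points, c("y_um", "z_um"), "aligned table")
  yz <- unique(cbind(points$y_um, points$z_um))
  if (nrow(yz) < 6) vm_stop("need at least 6 distinct (y, z) points to fit a conic")
  y <- yz[, 1]; z <- yz[, 2]
  sv <- svd(cbind(y - mean(y), z - mean(z)), nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    vm_stop("degenerate conic: transverse points are collinear")
  }
  coef <- switch(kind,
    ellipse = fit_conic_ellipse(y, z),
    hyperbola = fit_conic_general(y, z),
    auto = fit_conic_general(y, z))
  par <- conic_parameters(coef)
  if (kind == "ellipse" && par$kind != "ellipse") {
    vm_stop("ellipse fit did not return an ellipse")
  }
  if (kind == "hyperbola" && par$kind != "hyperbola") {
    vm_stop("requested hyperbola but the best-fitting conic is an ellipse")
  }
  if (kind == "auto" && par$kind == "ellipse") {
    coef <- fit_conic_ellipse(y, z)
    par <- conic_parameters(coef)
  }
  structure(
    list(kind = par$kind, center = par$center, semi_axes = par$semi_axes,
         tilt = par$tilt, fit_rms = sqrt(mean(conic_sampson(coef, y, z)^2)),
         coef = coef, n_points = nrow(yz)),
    class = "vm_conic")
}

#' @export
print.vm_conic <- function(x, ...) {
  cat(sprintf("<vm_conic> %s: center (%.3f, %.3f) µm, semi-axes (%.3f, %.3f) µm, tilt %.2f deg, fit RMS %.4g µm (n = %d)\n",
              x$kind, x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
              x$tilt * 180 / pi, x$fit_rms, x$n_points))
  invisible(x)
}

# Seam and signed arc length for one cell's projected parameters.
unroll_one_cell <- function(model, x, y, z, radial_tol, cell_id) {
  par <- model[c("kind", "center", "semi_axes", "tilt")]
  proj <- conic_project(par, y, z)
  band <- radial_tol * mean(par$semi_axes)
  bad <- which(proj$dist > band)
  if (length(bad)) {
    vm_stop(sprintf(
      "cell %s: %d point(s) outside the radial tolerance band (%.2f µm) of the fitted conic; offending point indices: %s",
      cell_id, length(bad), band, paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (par$kind == "ellipse") {
    t <- proj$t %% (2 * pi)
    # self-wrap check on the ordered, unwrapped parameter
    dt <- diff(t)
    dtw <- ((dt + pi) %% (2 * pi)) - pi
    tun <- t[1] + c(0, cumsum(dtw))
    if (diff(range(tun)) >= 2 * pi) {
      vm_stop(sprintf("cell %s: angular span >= 2*pi (outline wraps the vessel); cannot unroll", cell_id))
    }
    # seam at the midpoint of the largest angular gap of this cell's points
    st <- sort(t)
    gaps <- diff(c(st, st[1] + 2 * pi))
    gi <- which.max(gaps)
    seam <- (st[gi] + gaps[gi] / 2) %% (2 * pi)
    tp <- (t - seam) %% (2 * pi)
    S <- conic_arclength_fun(par, 0, 2 * pi)
    total <- S(2 * pi)
    # arc length from the seam, additive over the period
    s <- ifelse(seam + tp <= 2 * pi,
                S(seam + tp) - S(seam),
                total - S(seam) + S(seam + tp - 2 * pi))
  } else {
    if (length(unique(proj$branch)) > 1) {
      vm_stop(sprintf("cell %s: points project onto both hyperbola branches; cannot unroll", cell_id))
    }
    t <- proj$t
    lo <- min(t, 0) - 0.1; hi <- max(t, 0) + 0.1
    S <- conic_arclength_fun(par, lo, hi)
    s <- S(t) - S(0) # signed arc length from the vertex (t = 0)
  }
  tibble::tibble(x_um = x, s_um = s)
}

#' Unroll aligned outlines along a fitted cross-section
#'
#' Each point's transverse (y, z) position is replaced by the signed arc
#' length along the conic from a per-cell reference angle to the point's
#' nearest-point projection; the axial coordinate passes through unchanged.
#' The arc-length seam of a closed (ellipse) section is placed in the middle
#' of the largest angular gap of the cell's own points, so `s` is continuous
#' within every cell.
#'
#' @param points Aligned outline tibble (`cell_id`, `point_index`, `x_um`,
#'   `y_um`, `z_um`, plus any metadata columns, which are carried through).
#' @param model A `vm_conic` from [fit_cross_section()].
#' @param radial_tol Tolerance band for the projection distance, as a
#'   fraction of the mean semi-axis (default 0.2); points outside it raise an
#'   error naming the offending indices.
#' @return Tibble with `cell_id`, `point_index`, `x_um`, `s_um` and metadata.
#' @export
unroll_outlines <- function(points, model, radial_tol = 0.2) {
  check_columns(points, c("cell_id", "point_index", "x_um", "y_um", "z_um"),
                "aligned table")
  if (!inherits(model, "vm_conic")) vm_stop("`model` must be a vm_conic")
  meta <- intersect(c("group", vm_meta_cols), names(points))
  points |>
    dplyr::arrange(.data$cell_id, .data$point_index) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      un <- unroll_one_cell(model, df$x_um, df$y_um, df$z_um, radial_tol,
                            key$cell_id)
      dplyr::bind_cols(
        tibble::tibble(point_index = df$point_index,
                       x_um = un$x_um, s_um = un$s_um),
        df[1, meta][rep(1, nrow(df)), , drop = FALSE])
    }) |>
    dplyr::ungroup()
}

#' Align, fit and unroll a whole cohort
#'
#' Convenience wrapper chaining [estimate_centerline()], [align_outlines()],
#' [fit_cross_section()] and [unroll_outlines()] for each vessel segment.
#' With `fit_scope = "vessel"` one conic is fitted per segment from the
#' pooled points of all its cells; `"cell"` refits per cell (useful on
#' tapered vessels).
#'
#' @param outlines Outline tibble (e.g. `make_cohort(...)$outlines`).
#' @param by Column(s) identifying a vessel segment; defaults to `"group"`
#'   if present, else the metadata columns.
#' @param kind,radial_tol Passed to [fit_cross_section()] /
#'   [unroll_outlines()].
#' @param fit_scope `"vessel"` (default) or `"cell"`.
#' @return Unrolled tibble; fitted models are attached as attribute
#'   `"models"` (a named list) and frames as `"frames"`.
#' @export
unroll_cohort <- function(outlines, by = NULL,
                          kind = c("auto", "ellipse", "hyperbola"),
                          fit_scope = c("vessel", "cell"), radial_tol = 0.2) {
  kind <- match.arg(kind)
  fit_scope <- match.arg(fit_scope)
  if (is.null(by)) {
    by <- if ("group" %in% names(outlines)) "group" else
      intersect(vm_meta_cols, names(outlines))
    if (!length(by)) vm_stop("no grouping columns found; pass `by`")
  }
  keys <- outlines |> dplyr::distinct(dplyr::across(dplyr::all_of(by)))
  models <- list(); frames <- list(); parts <- list()
  for (i in seq_len(nrow(keys))) {
    seg <- dplyr::semi_join(outlines, keys[i, , drop = FALSE], by = by)
    label <- paste(unlist(keys[i, ]), collapse = "/")
    frame <- estimate_centerline(seg)
    aligned <- align_outlines(seg, frame)
    frames[[label]] <- frame
    if (fit_scope == "vessel") {
      model <- fit_cross_section(aligned, kind)
      models[[label]] <- model
      parts[[label]] <- unroll_outlines(aligned, model, radial_tol)
    } else {
      sub <- split(aligned, aligned$cell_id)
      out <- lapply(names(sub), function(cid) {
        m <- fit_cross_section(sub[[cid]], kind)
        models[[paste(label, cid, sep = "/")]] <<- m
        unroll_outlines(sub[[cid]], m, radial_tol)
      })
      parts[[label]] <- dplyr::bind_rows(out)
    }
  }
  res <- dplyr::bind_rows(parts)
  attr(res, "models") <- models
  attr(res, "frames") <- frames
  res
}
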