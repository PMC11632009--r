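#' @importFrom rlang abort warn %||% .data
#' @importFrom stats cov integrate optimize prcomp qchisq quantile rnorm
#'   runif sd setNames splinefun var rlnorm median
NULL

vm_stop <- function(msg, class = "vesselmorph_error") {
  abort(msg, class = class)
}

#' Fold an angle onto the unsigned alignment range
#'
#' An undirected axis is only defined modulo 180 degrees, and an unsigned
#' deviation from the vessel axis is only defined on \[0, 90\]: 120 degrees
#' folds to 60, -30 folds to 30.
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Angles folded into \[0, 90\] degrees.
#' @export
#' @examples
#' fold_angle(c(-30, 120, 95, 180))
fold_angle <- function(deg) {
  x <- deg %% 180
  ifelse(x > 90, 180 - x, x)
}

# Shoelace area of a polygon given as ordered vertices (closed implicitly).
polygon_area <- function(x, y) {
  n <- length(x)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  i2 <- c(2:n, 1)
  sum(sqrt((x[i2] - x)^2 + (y[i2] - y)^2))
}

# Proper-crossing test between all non-adjacent edge pairs of a closed
# polyline. O(n^2) on ~100-point outlines; exact for the warning it feeds.
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  if (n < 4) return(FALSE)
  i2 <- c(2:n, 1)
  ax <- x; ay <- y; bx <- x[i2]; by <- y[i2]
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)] # skip edges sharing a vertex
    if (!length(js)) next
    d1 <- cross(ax[i], ay[i], bx[i], by[i], ax[js], ay[js])
    d2 <- cross(ax[i], ay[i], bx[i], by[i], bx[js], by[js])
    d3 <- cross(ax[js], ay[js], bx[js], by[js], ax[i], ay[i])
    d4 <- cross(ax[js], ay[js], bx[js], by[js], bx[i], by[i])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# Metadata columns carried through every per-cell table.
vm_meta_cols <- c("vessel", "region", "stage_hpf", "genotype", "embryo_id")

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    vm_stop(sprintf("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Derive a stream-specific 32-bit seed from a base seed, so independent
# groups/cells draw from decoupled streams while staying reproducible.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647)
}
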