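# Internal polygon primitives.
#
# A contour is an n x 2 numeric matrix of vertices (x_mm, y_mm), implicitly
# closed (the last vertex connects back to the first).  All public entry
# points normalize orientation to counterclockwise, so downstream code can
# rely on positive signed area.

.poly_check <- function(xy, what = "contour") {
  if (!is.matrix(xy) || ncol(xy) != 2L || !is.numeric(xy))
    stop(what, " must be a numeric n x 2 matrix of (x_mm, y_mm) vertices")
  if (nrow(xy) < 3L)
    stop(what, " must have at least 3 vertices, got ", nrow(xy))
  if (!all(is.finite(xy)))
    stop(what, " contains non-finite coordinates")
  invisible(xy)
}

.poly_signed_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

.poly_area <- function(xy) abs(.poly_signed_area(xy))

# Normalize to counterclockwise vertex order.
.poly_ccw <- function(xy) {
  if (.poly_signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

.poly_centroid <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

.poly_edge_lengths <- function(xy) {
  nxt <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE])
  sqrt(rowSums((nxt - xy)^2))
}

.poly_perimeter <- function(xy) sum(.poly_edge_lengths(xy))

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
.points_in_poly <- function(px, py, xy) {
  n <- nrow(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y2[i] > py))
    if (any(crosses)) {
      xint <- x[i] + (py[crosses] - y[i]) / (y2[i] - y[i]) * (x2[i] - x[i])
      hit <- xint > px[crosses]
      idx <- which(crosses)[hit]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# Parametric intersections of m rays from a common origin with the edges of
# a polygon.  Rays are given by unit direction rows of D (m x 2); for ray j
# and edge i the intersection point is origin + t[j, i] * D[j, ].  Entries
# are NA where the ray and edge do not meet (edge parameter s outside
# [0, 1), parallel, or t <= 0).  The half-open s-range counts a crossing at
# a shared vertex exactly once.
.ray_poly_t <- function(origin, D, xy, eps = 1e-12) {
  A <- xy
  B <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE])
  E <- B - A
  AOx <- A[, 1L] - origin[1L]
  AOy <- A[, 2L] - origin[2L]
  denom <- outer(D[, 1L], E[, 2L]) - outer(D[, 2L], E[, 1L])   # cross(d_j, E_i)
  cAOE <- AOx * E[, 2L] - AOy * E[, 1L]                        # cross(AO_i, E_i)
  tmat <- matrix(cAOE, nrow(D), nrow(A), byrow = TRUE) / denom
  smat <- (outer(D[, 2L], AOx) - outer(D[, 1L], AOy)) / denom  # cross(AO_i, d_j)/denom
  # The s-tolerance keeps rays through a shared vertex from being rejected
  # by both adjacent edges through rounding; a doubled hit only duplicates a
  # t value, which per-ray min/max consumers are insensitive to.
  bad <- !is.finite(tmat) | abs(denom) < eps | smat < -1e-9 | smat >= 1 | tmat <= eps
  tmat[bad] <- NA_real_
  tmat
}

# Row-wise min / max of a matrix with NAs, returning NA for empty rows.
.row_min <- function(m) {
  out <- suppressWarnings(apply(m, 1L, min, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  out
}
.row_max <- function(m) {
  out <- suppressWarnings(apply(m, 1L, max, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  out
}

# Resample a closed polygon at arc-length positions `s` (measured from the
# first vertex, counterclockwise).  Returns a length(s) x 2 matrix.
.poly_point_at_arclength <- function(xy, s) {
  el <- .poly_edge_lengths(xy)
  cum <- c(0, cumsum(el))
  total <- cum[length(cum)]
  s <- s %% total
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > nrow(xy)] <- nrow(xy)
  frac <- (s - cum[idx]) / el[idx]
  frac[!is.finite(frac)] <- 0
  nxt <- c(seq_len(nrow(xy))[-1L], 1L)
  xy[idx, , drop = FALSE] + frac * (xy[nxt[idx], , drop = FALSE] - xy[idx, , drop = FALSE])
}
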