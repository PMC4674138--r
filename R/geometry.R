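#' Segmented cross-section geometry
#'
#' Bundle the segmented contours of one vessel cross-section: the lumen
#' boundary, the outer wall boundary, and zero or more lipid-rich necrotic
#' core and calcification contours.  All coordinates are slice-local
#' Cartesian millimetres.  Contours are normalized to counterclockwise
#' orientation on construction, so vertex order of the inputs does not
#' affect any downstream measurement.
#'
#' @param lumen,outer n x 2 numeric matrices of (x_mm, y_mm) vertices of the
#'   lumen and outer wall boundaries (closed polygons; the last vertex
#'   connects back to the first).
#' @param lipid_cores,calcifications lists of n x 2 vertex matrices for
#'   plaque components lying within the wall annulus.
#' @param patient_id,slice_id identifiers carried through to all outputs.
#' @param validate if `TRUE` (default), check containment: the lumen must lie
#'   strictly inside the outer boundary and every component inside the wall
#'   annulus (inside outer, outside lumen).
#' @return An object of class `slice_geometry`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 129)[-129]
#' lumen <- cbind(1.5 * cos(th), 1.5 * sin(th))
#' outer <- cbind(2.5 * cos(th), 2.5 * sin(th))
#' geom <- slice_geometry(lumen, outer)
#' @export
slice_geometry <- function(lumen, outer, lipid_cores = list(),
                           calcifications = list(),
                           patient_id = "P0", slice_id = "S0",
                           validate = TRUE) {
  .poly_check(lumen, "lumen"); .poly_check(outer, "outer boundary")
  lumen <- .poly_ccw(lumen); outer <- .poly_ccw(outer)
  lipid_cores <- lapply(seq_along(lipid_cores), function(i) {
    .poly_ccw(.poly_check(lipid_cores[[i]], paste0("lipid core ", i)))
  })
  calcifications <- lapply(seq_along(calcifications), function(i) {
    .poly_ccw(.poly_check(calcifications[[i]], paste0("calcification ", i)))
  })
  geom <- structure(
    list(patient_id = patient_id, slice_id = slice_id,
         lumen = lumen, outer = outer,
         lipid_cores = lipid_cores, calcifications = calcifications),
    class = "slice_geometry")
  if (validate) .check_containment(geom)
  geom
}

# Containment validation: lumen vertices strictly inside the outer polygon;
# component vertices inside outer and outside the lumen.  Vertex-level tests
# are adequate for the simple, smooth contours this package deals with.
.check_containment <- function(geom) {
  id <- paste0(geom$patient_id, "/", geom$slice_id)
  if (.poly_area(geom$outer) <= .poly_area(geom$lumen))
    stop("slice ", id, ": outer boundary area must exceed lumen area")
  if (!all(.points_in_poly(geom$lumen[, 1L], geom$lumen[, 2L], geom$outer)))
    stop("slice ", id, ": lumen is not contained in the outer boundary")
  comps <- c(geom$lipid_cores, geom$calcifications)
  roles <- c(rep("lipid core", length(geom$lipid_cores)),
             rep("calcification", length(geom$calcifications)))
  for (i in seq_along(comps)) {
    xy <- comps[[i]]
    if (!all(.points_in_poly(xy[, 1L], xy[, 2L], geom$outer)))
      stop("slice ", id, ": ", roles[i], " extends outside the outer boundary")
    if (any(.points_in_poly(xy[, 1L], xy[, 2L], geom$lumen)))
      stop("slice ", id, ": ", roles[i], " intrudes into the lumen")
  }
  invisible(geom)
}

#' @export
print.slice_geometry <- function(x, ...) {
  cat("<slice_geometry> patient", x$patient_id, "slice", x$slice_id, "\n")
  cat("  lumen area:", format(.poly_area(x$lumen), digits = 4), "mm^2;",
      "outer area:", format(.poly_area(x$outer), digits = 4), "mm^2\n")
  cat("  components:", length(x$lipid_cores), "lipid core(s),",
      length(x$calcifications), "calcification(s)\n")
  invisible(x)
}

#' Sample evenly spaced nodal points on the lumen in four quarters
#'
#' Places `n_nodes` points on the lumen boundary, evenly spaced by arc
#' length, and tags each with a quarter id.  The arc-length origin is the
#' lumen vertex with maximum x (ties broken by maximum y), and the four
#' quarters are the four equal arc-length segments of the lumen perimeter
#' starting there, so each quarter receives exactly `n_nodes / 4` points.
#'
#' @param geom a [slice_geometry()].
#' @param n_nodes number of nodal points; must be divisible by 4.
#'   Default 100 (25 per quarter).
#' @return A data frame with columns `node_idx`, `quarter` (1..4), `x_mm`,
#'   `y_mm`.
#' @export
sample_nodal_points <- function(geom, n_nodes = 100L) {
  stopifnot(inherits(geom, "slice_geometry"))
  if (n_nodes %% 4L != 0L || n_nodes < 8L)
    stop("n_nodes must be a positive multiple of 4")
  lum <- geom$lumen
  if (.poly_area(lum) < 1e-6)
    stop("degenerate lumen: area below tolerance (1e-6 mm^2)")
  # rotate vertex order so the max-x (then max-y) vertex comes first
  ord <- order(-lum[, 1L], -lum[, 2L])
  start <- ord[1L]
  lum <- lum[c(start:nrow(lum), seq_len(start - 1L)), , drop = FALSE]
  per <- .poly_perimeter(lum)
  s <- (seq_len(n_nodes) - 1L) / n_nodes * per
  pts <- .poly_point_at_arclength(lum, s)
  data.frame(node_idx = seq_len(n_nodes),
             quarter = (seq_len(n_nodes) - 1L) %/% (n_nodes %/% 4L) + 1L,
             x_mm = pts[, 1L], y_mm = pts[, 2L])
}

#' Connecting line from a lumen point to the outer boundary
#'
#' Realizes the correspondence between lumen nodal points and outer-boundary
#' points by centroid-ray casting: the outer point is the first intersection
#' of the ray from the lumen centroid through the lumen point with the outer
#' boundary.  The segment length is the wall thickness at that node.  For a
#' non-star-shaped lumen (the centroid ray crosses the lumen boundary more
#' than once) the farthest lumen crossing is used as the effective lumen
#' point and the result carries attribute `non_star = TRUE`.
#'
#' @param geom a [slice_geometry()].
#' @param lumen_point numeric length-2 point on the lumen boundary (mm).
#' @return A list with `lumen_point`, `outer_point`, `direction` (unit
#'   vector), `length_mm` and `r_lumen_mm` (distance centroid to lumen
#'   point).
#' @export
connecting_line <- function(geom, lumen_point) {
  stopifnot(inherits(geom, "slice_geometry"), length(lumen_point) == 2L)
  O <- .poly_centroid(geom$lumen)
  v <- as.numeric(lumen_point) - O
  r0 <- sqrt(sum(v^2))
  if (r0 < 1e-9) stop("lumen point coincides with the lumen centroid")
  D <- matrix(v / r0, 1L, 2L)
  t_lum <- .row_max(.ray_poly_t(O, D, geom$lumen))
  non_star <- FALSE
  if (is.na(t_lum)) {
    t_lum <- r0
  } else if (abs(t_lum - r0) > 1e-6) {
    non_star <- TRUE
  }
  t_out <- .ray_poly_t(O, D, geom$outer)
  t_out <- suppressWarnings(min(t_out[1L, ][t_out[1L, ] > t_lum + 1e-9], na.rm = TRUE))
  if (!is.finite(t_out))
    stop("slice ", geom$patient_id, "/", geom$slice_id,
         ": centroid ray misses the outer boundary (invalid containment)")
  structure(list(lumen_point = O + t_lum * D[1L, ],
                 outer_point = O + t_out * D[1L, ],
                 direction = D[1L, ],
                 length_mm = t_out - t_lum,
                 r_lumen_mm = t_lum),
            non_star = non_star)
}

#' Fibrous-cap thickness along a connecting line
#'
#' Measures cap thickness along one wall-thickness segment: if the segment
#' crosses a lipid core, the cap thickness is the distance from the lumen
#' point to the first (nearest) lipid-core crossing; otherwise the full
#' segment length, i.e. the wall thickness.  Calcifications never shorten
#' the measurement.
#'
#' @param geom a [slice_geometry()].
#' @param segment a connecting line from [connecting_line()].
#' @return A list with `cap_thickness_mm` and `hits_lipid`.
#' @export
cap_thickness <- function(geom, segment) {
  stopifnot(inherits(geom, "slice_geometry"))
  O <- segment$lumen_point
  D <- matrix(segment$direction, 1L, 2L)
  len <- segment$length_mm
  best <- Inf
  for (core in geom$lipid_cores) {
    tt <- .ray_poly_t(O, D, core)[1L, ]
    tt <- tt[!is.na(tt) & tt <= len + 1e-9]
    if (length(tt)) best <- min(best, min(tt))
  }
  if (is.finite(best)) {
    list(cap_thickness_mm = best, hits_lipid = TRUE)
  } else {
    list(cap_thickness_mm = len, hits_lipid = FALSE)
  }
}

#' Nodal wall- and cap-thickness profile of a slice
#'
#' The per-slice measurement driver: samples the nodal points
#' ([sample_nodal_points()]), casts the centroid ray through each, and
#' records wall thickness, cap thickness and the lipid-hit flag at every
#' node.  All rays are intersected with the contours in one vectorized pass.
#'
#' @param geom a [slice_geometry()].
#' @param n_nodes number of nodal points (multiple of 4), default 100.
#' @return A data frame with one row per node and columns `node_idx`,
#'   `quarter`, `lumen_x_mm`, `lumen_y_mm`, `outer_x_mm`, `outer_y_mm`,
#'   `r_lumen_mm`, `wall_mm`, `cap_mm`, `hits_lipid`.  The number of
#'   non-star-shaped rays (farthest lumen crossing used) is carried as
#'   attribute `n_non_star`.
#' @export
nodal_profile <- function(geom, n_nodes = 100L) {
  pts <- sample_nodal_points(geom, n_nodes)
  O <- .poly_centroid(geom$lumen)
  V <- cbind(pts$x_mm - O[1L], pts$y_mm - O[2L])
  r0 <- sqrt(rowSums(V^2))
  if (any(r0 < 1e-9)) stop("nodal point coincides with the lumen centroid")
  D <- V / r0
  t_lum <- .row_max(.ray_poly_t(O, D, geom$lumen))
  miss <- is.na(t_lum)
  t_lum[miss] <- r0[miss]
  n_non_star <- sum(abs(t_lum - r0) > 1e-6)
  tmat <- .ray_poly_t(O, D, geom$outer)
  tmat[tmat <= t_lum + 1e-9] <- NA_real_
  t_out <- .row_min(tmat)
  if (anyNA(t_out))
    stop("slice ", geom$patient_id, "/", geom$slice_id,
         ": centroid ray misses the outer boundary (invalid containment)")
  wall <- t_out - t_lum
  cap <- wall
  hits <- rep(FALSE, n_nodes)
  for (core in geom$lipid_cores) {
    tc <- .ray_poly_t(O, D, core)
    tc[tc <= t_lum + 1e-9 | tc > t_out + 1e-9] <- NA_real_
    tfirst <- .row_min(tc)
    hit <- !is.na(tfirst)
    cap[hit] <- pmin(cap[hit], tfirst[hit] - t_lum[hit])
    hits <- hits | hit
  }
  out <- data.frame(node_idx = pts$node_idx, quarter = pts$quarter,
                    lumen_x_mm = O[1L] + t_lum * D[, 1L],
                    lumen_y_mm = O[2L] + t_lum * D[, 2L],
                    outer_x_mm = O[1L] + t_out * D[, 1L],
                    outer_y_mm = O[2L] + t_out * D[, 2L],
                    r_lumen_mm = t_lum,
                    wall_mm = wall,
                    cap_mm = pmin(cap, wall),
                    hits_lipid = hits)
  attr(out, "n_non_star") <- n_non_star
  out
}

#' Per-slice morphology scalars
#'
#' Computes the slice-level morphological summary: minimum cap thickness
#' over the nodal profile, contour areas by the shoelace formula, and the
#' lipid percentage, defined as the total lipid-core area divided by the
#' wall area (outer-boundary area minus lumen area).  Lipid-core area is
#' counted in full even where a core overlaps a calcification.
#'
#' @param geom a [slice_geometry()].
#' @param profile optional precomputed [nodal_profile()] of `geom`.
#' @return A list of class `slice_morphology` with `min_cap_thickness_mm`,
#'   `lipid_fraction` (in \[0, 1)), `lumen_area_mm2`, `outer_area_mm2`,
#'   `lipid_area_mm2`, `has_lipid`.
#' @export
slice_morphology <- function(geom, profile = NULL) {
  stopifnot(inherits(geom, "slice_geometry"))
  if (is.null(profile)) profile <- nodal_profile(geom)
  lumen_a <- .poly_area(geom$lumen)
  outer_a <- .poly_area(geom$outer)
  if (outer_a <= lumen_a)
    stop("slice ", geom$patient_id, "/", geom$slice_id,
         ": outer area must exceed lumen area")
  lipid_a <- sum(vapply(geom$lipid_cores, .poly_area, numeric(1)))
  structure(list(min_cap_thickness_mm = min(profile$cap_mm),
                 lipid_fraction = lipid_a / (outer_a - lumen_a),
                 lumen_area_mm2 = lumen_a,
                 outer_area_mm2 = outer_a,
                 lipid_area_mm2 = lipid_a,
                 has_lipid = lipid_a > 0),
            class = "slice_morphology")
}
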