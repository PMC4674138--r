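# Fixture builders and independent oracles shared across tests.

# Circle contour (optionally off-centre), counterclockwise.
circle_xy <- function(r, cx = 0, cy = 0, n = 128L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

ellipse_xy <- function(a, b, n = 128L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(a * cos(th), b * sin(th))
}

# Concentric-circle slice with an optional annular-sector lipid core at a
# given cap offset from the lumen: the core spans angles [a0, a1], its inner
# edge at radius r_lumen + cap, outer edge at r_lumen + cap + thick.
sector_xy <- function(r_inner, thick, a0, a1, n = 64L) {
  ang <- seq(a0, a1, length.out = n)
  rbind(cbind(r_inner * cos(ang), r_inner * sin(ang)),
        cbind((r_inner + thick) * cos(rev(ang)), (r_inner + thick) * sin(rev(ang))))
}

annulus_slice <- function(r = 1.5, wall = 1.0, cap = NULL, lipid_arc = c(0, pi / 2),
                          lipid_thick = 0.4, calc = FALSE, n = 128L, ...) {
  cores <- list()
  if (!is.null(cap))
    cores <- list(sector_xy(r + cap, lipid_thick, lipid_arc[1L], lipid_arc[2L]))
  calcs <- if (calc)
    list(sector_xy(r + 0.45, 0.2, pi, pi + pi / 3)) else list()
  slice_geometry(circle_xy(r, n = n), circle_xy(r + wall, n = n),
                 cores, calcs, ...)
}

# Brute-force oracle: cap thickness along the segment p0 -> p1, solving the
# 2x2 segment-segment system for every lipid-core edge by Cramer's rule
# (both parameters constrained to the closed unit interval).
oracle_cap <- function(geom, p0, p1) {
  d <- p1 - p0
  L <- sqrt(sum(d^2))
  best <- Inf
  for (core in geom$lipid_cores) {
    a <- core
    b <- rbind(core[-1L, , drop = FALSE], core[1L, , drop = FALSE])
    ex <- a[, 1L] - b[, 1L]; ey <- a[, 2L] - b[, 2L]   # columns of [d, a-b]
    dt <- d[1L] * ey - ex * d[2L]
    rx <- a[, 1L] - p0[1L]; ry <- a[, 2L] - p0[2L]
    s <- (rx * ey - ex * ry) / dt
    t <- (d[1L] * ry - d[2L] * rx) / dt
    ok <- abs(dt) > 1e-14 & is.finite(s) & is.finite(t) &
      s >= 0 & s <= 1 & t >= 0 & t <= 1
    if (any(ok)) best <- min(best, min(s[ok]) * L)
  }
  if (is.finite(best)) list(cap = best, hit = TRUE)
  else list(cap = L, hit = FALSE)
}

# Brute-force arc-length coordinate of a point lying on a polygon boundary.
oracle_arc_position <- function(xy, p, tol = 1e-9) {
  n <- nrow(xy)
  acc <- 0
  for (i in seq_len(n)) {
    a <- xy[i, ]; b <- xy[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    u <- (b - a) / len
    t <- sum((p - a) * u)
    if (t >= -tol && t <= len + tol) {
      perp <- (p - a) - t * u
      if (sqrt(sum(perp^2)) < 1e-7) return(acc + min(max(t, 0), len))
    }
    acc <- acc + len
  }
  NA_real_
}

# Exhaustive stress-interval calibration (independent check of the dynamic
# program): enumerate every non-decreasing boundary vector b1<=b2<=b3<=b4
# over block positions 0..u (equal entries mean an empty index level) and
# count exact matches.  Returns the best match count and the
# lexicographically smallest optimal boundary vector.
oracle_calibrate <- function(cpws, morph) {
  v <- sort(unique(cpws)); u <- length(v); block <- match(cpws, v)
  cnt <- sapply(0:4, function(l) tabulate(block[morph == l], nbins = u))
  pre <- rbind(0, apply(cnt, 2, cumsum))      # pre[j+1, l] = level-l slices in blocks 1..j
  E <- utils::combn(0:(u + 3L), 4L)           # strictly increasing in 0..u+3
  B <- E - (seq_len(4L) - 1L)                 # non-decreasing in 0..u
  tot <- pre[B[1L, ] + 1L, 1L] +
    (pre[B[2L, ] + 1L, 2L] - pre[B[1L, ] + 1L, 2L]) +
    (pre[B[3L, ] + 1L, 3L] - pre[B[2L, ] + 1L, 3L]) +
    (pre[B[4L, ] + 1L, 4L] - pre[B[3L, ] + 1L, 4L]) +
    (pre[u + 1L, 5L] - pre[B[4L, ] + 1L, 5L])
  best <- max(tot)
  k <- which(tot == best)
  Bk <- B[, k, drop = FALSE]
  lex <- Bk[, do.call(order, as.data.frame(t(Bk)))[1L]]
  list(matched = best, boundaries = lex)
}

# Minimal hand-built nodal profile for surrogate tests.
fake_profile <- function(n = 100L, r = 1.5, wall = 1.0, cap = wall,
                         hits = rep(FALSE, n)) {
  cap <- rep_len(cap, n); wall <- rep_len(wall, n)
  data.frame(node_idx = seq_len(n),
             quarter = (seq_len(n) - 1L) %/% (n %/% 4L) + 1L,
             lumen_x_mm = 0, lumen_y_mm = 0, outer_x_mm = 0, outer_y_mm = 0,
             r_lumen_mm = rep_len(r, n), wall_mm = wall,
             cap_mm = ifelse(hits, cap, wall), hits_lipid = hits)
}
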