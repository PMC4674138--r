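test_that("nodal points are evenly spaced by arc length with 25 per quarter", {
  g <- annulus_slice()
  pts <- sample_nodal_points(g)
  expect_equal(nrow(pts), 100L)
  expect_equal(unname(table(pts$quarter)), rep(25L, 4L), ignore_attr = TRUE)

  # arc-length coordinates (relative to the max-x start vertex) must advance
  # by exactly perimeter/100, checked against a brute-force point locator
  lum <- g$lumen
  start <- which.max(lum[, 1L] * 1e9 + lum[, 2L])
  lum <- lum[c(start:nrow(lum), seq_len(start - 1L)), ]
  per <- sum(sqrt(rowSums((rbind(lum[-1, ], lum[1, ]) - lum)^2)))
  s <- vapply(seq_len(100L), function(k)
    oracle_arc_position(lum, c(pts$x_mm[k], pts$y_mm[k])), numeric(1))
  expect_equal(s, (0:99) / 100 * per, tolerance = 1e-9)
})

test_that("corner-heavy polygons are sampled by arc length, not vertex index", {
  sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  # duplicate-corner-free square with extra vertices crowded on one side
  crowded <- rbind(c(1, 1), cbind(seq(0.9, -0.9, length.out = 50), 1),
                   c(-1, 1), c(-1, -1), c(1, -1))
  g <- slice_geometry(crowded, 3 * sq, validate = FALSE)
  pts <- sample_nodal_points(g)
  lum <- g$lumen
  start <- which.max(lum[, 1L] * 1e9 + lum[, 2L])
  lum <- lum[c(start:nrow(lum), seq_len(start - 1L)), ]
  s <- vapply(seq_len(100L), function(k)
    oracle_arc_position(lum, c(pts$x_mm[k], pts$y_mm[k])), numeric(1))
  expect_equal(s, (0:99) / 100 * 8, tolerance = 1e-9)
})

test_that("connecting lines are centroid rays; concentric and eccentric oracles", {
  g <- annulus_slice(r = 1.5, wall = 1.0, n = 512L)
  pr <- nodal_profile(g)
  expect_equal(pr$wall_mm, rep(1.0, 100L), tolerance = 1e-4)

  # outer circle centre offset by 0.3 mm: closed-form ray-circle intersection
  g2 <- slice_geometry(circle_xy(1.5, n = 512L), circle_xy(2.5, cx = 0.3, n = 512L))
  pr2 <- nodal_profile(g2)
  ang <- atan2(pr2$lumen_y_mm, pr2$lumen_x_mm)
  d <- cbind(cos(ang), sin(ang))
  texp <- d[, 1L] * 0.3 + sqrt(2.5^2 - 0.3^2 + (d[, 1L] * 0.3)^2)
  expect_equal(pr2$wall_mm, texp - 1.5, tolerance = 5e-4)
  expect_lt(min(pr2$wall_mm), 0.705)
  expect_gt(max(pr2$wall_mm), 1.295)

  seg <- connecting_line(g, c(1.5, 0))
  expect_equal(seg$length_mm, 1.0, tolerance = 1e-3)
  expect_equal(seg$r_lumen_mm, 1.5, tolerance = 1e-3)
})

test_that("cap thickness is the first lipid crossing; calcification never counts", {
  # core entered at 0.12 mm from the lumen over the first quadrant
  g <- annulus_slice(cap = 0.12, lipid_arc = c(0.2, pi / 2 - 0.2))
  seg <- connecting_line(g, c(1.5 * cos(0.7), 1.5 * sin(0.7)))
  ct <- cap_thickness(g, seg)
  expect_true(ct$hits_lipid)
  expect_equal(ct$cap_thickness_mm, 0.12, tolerance = 5e-3)

  # a node outside the lipid arc reports the full wall thickness
  seg2 <- connecting_line(g, c(1.5 * cos(pi), 1.5 * sin(pi)))
  ct2 <- cap_thickness(g, seg2)
  expect_false(ct2$hits_lipid)
  expect_equal(ct2$cap_thickness_mm, seg2$length_mm)

  # calcification-only crossing keeps the full wall thickness
  gc <- annulus_slice(calc = TRUE)
  segc <- connecting_line(gc, c(1.5 * cos(pi + 0.5), 1.5 * sin(pi + 0.5)))
  ctc <- cap_thickness(gc, segc)
  expect_false(ctc$hits_lipid)
  expect_equal(ctc$cap_thickness_mm, segc$length_mm, tolerance = 1e-9)

  # two cores crossed at 0.2 and 0.5 mm: the nearer one wins (vs brute force)
  g2 <- slice_geometry(circle_xy(1.5), circle_xy(2.5),
                       list(sector_xy(1.7, 0.15, -0.4, 0.4),
                            sector_xy(2.0, 0.2, -0.4, 0.4)))
  seg3 <- connecting_line(g2, c(1.5, 0.0001))
  ct3 <- cap_thickness(g2, seg3)
  o <- oracle_cap(g2, seg3$lumen_point, seg3$outer_point)
  expect_true(ct3$hits_lipid)
  expect_equal(ct3$cap_thickness_mm, o$cap, tolerance = 1e-9)
  expect_equal(ct3$cap_thickness_mm, 0.2, tolerance = 2e-3)
})

test_that("slice morphology implements the lipid-percentage ratio and min cap rule", {
  # annular-sector core of known analytic area inside a known annulus
  r <- 1.5; wall <- 1.0; cap <- 0.2; thick <- 0.4; a0 <- 0; a1 <- pi / 2
  g <- annulus_slice(r = r, wall = wall, cap = cap, lipid_arc = c(a0, a1),
                     lipid_thick = thick, n = 256L)
  pr <- nodal_profile(g)
  m <- slice_morphology(g, pr)
  sector_area <- (a1 - a0) / 2 * ((r + cap + thick)^2 - (r + cap)^2)
  annulus_area <- pi * ((r + wall)^2 - r^2)
  expect_equal(m$lipid_fraction, sector_area / annulus_area, tolerance = 5e-3)
  expect_equal(m$min_cap_thickness_mm, cap, tolerance = 2e-3)
  expect_true(m$has_lipid)
  expect_equal(m$lipid_fraction,
               m$lipid_area_mm2 / (m$outer_area_mm2 - m$lumen_area_mm2))

  # no lipid: percentage 0, min cap equals min wall thickness
  g0 <- annulus_slice()
  pr0 <- nodal_profile(g0)
  m0 <- slice_morphology(g0, pr0)
  expect_identical(m0$lipid_area_mm2, 0)
  expect_false(m0$has_lipid)
  expect_equal(m0$min_cap_thickness_mm, min(pr0$wall_mm))
})

test_that("shoelace areas match analytic values within 0.5% at 128 vertices", {
  expect_equal(plaquevuln:::.poly_area(circle_xy(1.5)), pi * 1.5^2,
               tolerance = 5e-3)
  expect_equal(plaquevuln:::.poly_area(ellipse_xy(2, 1)), 2 * pi,
               tolerance = 5e-3)
})

test_that("every node satisfies 0 < cap <= wall with equality iff no lipid hit", {
  set.seed(31)
  cfg <- cohort_config(n_patients = 1L, slices_per_patient = 12L, seed = 31L)
  for (s in seq_len(12L)) {
    pr <- nodal_profile(generate_slice(cfg))
    expect_true(all(pr$cap_mm > 0))
    expect_true(all(pr$cap_mm <= pr$wall_mm + 1e-12))
    expect_equal(pr$cap_mm[!pr$hits_lipid], pr$wall_mm[!pr$hits_lipid])
    expect_true(all(pr$cap_mm[pr$hits_lipid] < pr$wall_mm[pr$hits_lipid]))
  }
})

test_that("min cap thickness decreases as a core moves toward the lumen", {
  caps <- seq(0.28, 0.04, by = -0.04)
  mins <- vapply(caps, function(cp) {
    g <- annulus_slice(cap = cp)
    slice_morphology(g, nodal_profile(g))$min_cap_thickness_mm
  }, numeric(1))
  expect_true(all(diff(mins) < 0))
  expect_equal(mins, caps, tolerance = 2e-2)
})

test_that("reversing vertex order of any contour changes nothing", {
  g <- annulus_slice(cap = 0.1)
  rev_xy <- function(xy) xy[rev(seq_len(nrow(xy))), ]
  g2 <- slice_geometry(rev_xy(g$lumen), rev_xy(g$outer),
                       lapply(g$lipid_cores, rev_xy))
  expect_equal(nodal_profile(g), nodal_profile(g2), ignore_attr = TRUE)
  expect_equal(unclass(slice_morphology(g)), unclass(slice_morphology(g2)))
})

test_that("degenerate geometry is rejected with informative errors", {
  expect_error(slice_geometry(circle_xy(2.5), circle_xy(1.5)), "lumen")
  expect_error(slice_geometry(circle_xy(1.5), circle_xy(2.5),
                              list(sector_xy(2.6, 0.3, 0, 1))),
               "outside the outer boundary")
  expect_error(slice_geometry(rbind(c(0, 0), c(1, 0)), circle_xy(2.5)),
               "at least 3 vertices")
})
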