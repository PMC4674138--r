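test_that("Laplace wall stress and Poiseuille shear match hand calculations", {
  pr <- fake_profile(r = 1.5, wall = 1.0)
  sp <- surrogate_params(pressure_kPa = 13.3, viscosity_Pa_s = 0.0035, flow_ml_s = 1)
  mech <- nodal_mechanics(pr, params = sp)
  expect_equal(mech$pws_kPa, rep(13.3 * 1.5 / 1.0, 100))
  # tau = 4 mu Q / (pi r^3), SI, then 1 Pa = 10 dyn/cm^2
  tau <- 4 * 0.0035 * 1e-6 / (pi * (1.5e-3)^3) * 10
  expect_equal(mech$fss_dyn_cm2, rep(tau, 100))
  expect_true(all(mech$pwsn > 0 & mech$pwsn <= 0.5))
})

test_that("halving the cap thickness at one node doubles its wall stress only", {
  hits <- rep(FALSE, 100); hits[40:45] <- TRUE
  cap <- rep(1, 100); cap[40:45] <- 0.2
  pr1 <- fake_profile(cap = cap, hits = hits)
  cap2 <- cap; cap2[42] <- 0.1
  pr2 <- fake_profile(cap = cap2, hits = hits)
  sp <- surrogate_params()
  m1 <- nodal_mechanics(pr1, params = sp)
  m2 <- nodal_mechanics(pr2, params = sp)
  expect_equal(m2$pws_kPa[42], 2 * m1$pws_kPa[42])
  expect_equal(m2$pws_kPa[-42], m1$pws_kPa[-42])
})

test_that("critical values come from the dilated cap region", {
  hits <- rep(FALSE, 100); hits[20:30] <- TRUE
  pr <- fake_profile(hits = hits, cap = 0.2)
  mech <- data.frame(node_idx = 1:100,
                     pws_kPa = rep(50, 100), pwsn = rep(0.05, 100),
                     fss_dyn_cm2 = rep(12, 100))
  # single peak inside the cap arc
  mech$pws_kPa[25] <- 120
  cr <- extract_critical(mech, pr)
  expect_equal(cr$cpws_kPa, 120)
  expect_equal(unname(cr$critical_node_idx["pws"]), 25)

  # a larger value outside the cap+shoulder region is ignored
  mech$pws_kPa[70] <- 500
  expect_equal(extract_critical(mech, pr)$cpws_kPa, 120)

  # a shoulder node (2 outside the lipid arc) is eligible
  mech$pws_kPa[32] <- 200
  cr2 <- extract_critical(mech, pr)
  expect_equal(cr2$cpws_kPa, 200)
  expect_equal(unname(cr2$critical_node_idx["pws"]), 32)
  # ... but 3 nodes outside is not
  mech$pws_kPa[32] <- 50; mech$pws_kPa[33] <- 400
  expect_equal(extract_critical(mech, pr)$cpws_kPa, 120)

  # two lipid arcs: max of the per-arc peaks
  hits2 <- rep(FALSE, 100); hits2[10:20] <- TRUE; hits2[60:70] <- TRUE
  pr2 <- fake_profile(hits = hits2, cap = 0.2)
  mech2 <- mech; mech2$pws_kPa <- rep(50, 100)
  mech2$pws_kPa[15] <- 120; mech2$pws_kPa[65] <- 150
  expect_equal(extract_critical(mech2, pr2)$cpws_kPa, 150)

  # lipid-free slice: global maximum is used
  pr3 <- fake_profile()
  expect_equal(extract_critical(mech, pr3)$cpws_kPa, max(mech$pws_kPa))
})

test_that("critical extraction is invariant to rotation of the node array", {
  set.seed(5)
  hits <- rep(FALSE, 100); hits[90:100] <- TRUE; hits[1:5] <- TRUE  # wraps around
  pr <- fake_profile(hits = hits, cap = 0.15)
  mech <- data.frame(node_idx = 1:100, pws_kPa = runif(100, 20, 80),
                     pwsn = runif(100, 0.01, 0.2), fss_dyn_cm2 = runif(100, 5, 30))
  base <- extract_critical(mech, pr)
  for (k in c(13, 57)) {
    rot <- function(v) c(v[-(1:k)], v[1:k])
    pr_r <- pr; pr_r$hits_lipid <- rot(pr$hits_lipid); pr_r$cap_mm <- rot(pr$cap_mm)
    mech_r <- mech
    mech_r$pws_kPa <- rot(mech$pws_kPa); mech_r$pwsn <- rot(mech$pwsn)
    mech_r$fss_dyn_cm2 <- rot(mech$fss_dyn_cm2)
    cr <- extract_critical(mech_r, pr_r)
    expect_equal(cr$cpws_kPa, base$cpws_kPa)
    expect_equal(cr$cpwsn, base$cpwsn)
    expect_equal(cr$cfss_dyn_cm2, base$cfss_dyn_cm2)
  }
})

test_that("noise-free CPWS decreases with cap thickness, CFSS with lumen radius", {
  sp <- surrogate_params()
  caps <- seq(0.05, 0.29, by = 0.04)
  cpws <- vapply(caps, function(cp) {
    g <- annulus_slice(cap = cp)
    pr <- nodal_profile(g)
    extract_critical(nodal_mechanics(pr, g, sp), pr)$cpws_kPa
  }, numeric(1))
  expect_true(all(diff(cpws) < 0))

  radii <- seq(1.0, 2.2, by = 0.3)
  cfss <- vapply(radii, function(r) {
    g <- annulus_slice(r = r)
    pr <- nodal_profile(g)
    extract_critical(nodal_mechanics(pr, g, sp), pr)$cfss_dyn_cm2
  }, numeric(1))
  expect_true(all(diff(cfss) < 0))
})

test_that("multiplicative noise is seeded and positivity-preserving", {
  pr <- fake_profile()
  sp1 <- surrogate_params(coupling = list(a = 0, b = 1, noise_sd = 0.3), seed = 99)
  m1 <- nodal_mechanics(pr, params = sp1)
  m2 <- nodal_mechanics(pr, params = sp1)
  expect_identical(m1, m2)
  expect_true(all(m1$pws_kPa > 0) && all(m1$fss_dyn_cm2 > 0))
  sp2 <- surrogate_params(coupling = list(a = 0, b = 1, noise_sd = 0.3), seed = 100)
  expect_false(identical(m1, nodal_mechanics(pr, params = sp2)))
})
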