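test_that("cap index follows the right-closed thickness bins", {
  expect_identical(assign_cap_index(0.05, TRUE), 4L)
  expect_identical(assign_cap_index(0.065, TRUE), 4L)
  expect_identical(assign_cap_index(0.0650001, TRUE), 3L)
  expect_identical(assign_cap_index(0.15, TRUE), 3L)
  expect_identical(assign_cap_index(0.18, TRUE), 2L)
  expect_identical(assign_cap_index(0.2, TRUE), 2L)
  expect_identical(assign_cap_index(0.21, TRUE), 1L)
  expect_identical(assign_cap_index(0.25, FALSE), 0L)   # no component
  expect_identical(assign_cap_index(0.03, FALSE), 0L)
  expect_error(assign_cap_index(0, TRUE), "positive")
})

test_that("lipid index follows the percentage bins with strict 0", {
  expect_identical(assign_lipid_index(0), 0L)
  expect_identical(assign_lipid_index(2), 1L)
  expect_identical(assign_lipid_index(5), 2L)
  expect_identical(assign_lipid_index(29.999), 2L)
  expect_identical(assign_lipid_index(35), 3L)
  expect_identical(assign_lipid_index(40), 4L)
  expect_identical(assign_lipid_index(75), 4L)
  expect_error(assign_lipid_index(-1), "\\[0, 100\\)")
  expect_error(assign_lipid_index(100), "\\[0, 100\\)")
})

test_that("morphological index is the max of cap and lipid indices", {
  expect_identical(morphological_index(2L, 4L), 4L)
  expect_identical(morphological_index(0L, 0L), 0L)
  expect_identical(morphological_index(3L, 1L), 3L)
  expect_identical(morphological_index(c(1L, 4L), c(2L, 0L)), c(2L, 4L))
  expect_error(morphological_index(5L, 1L), "0\\.\\.4")
})

test_that("stress index uses left-open right-closed intervals", {
  expect_identical(assign_stress_index(100), 3L)
  expect_identical(assign_stress_index(35), 0L)
  expect_identical(assign_stress_index(35.001), 1L)
  expect_identical(assign_stress_index(140), 3L)
  expect_identical(assign_stress_index(200), 4L)
  expect_identical(assign_stress_index(c(10, 55, 89)), c(0L, 1L, 2L))
  expect_error(assign_stress_index(0), "positive")
  # monotone in CPWS for fixed intervals
  x <- sort(runif(50, 1, 300))
  expect_true(all(diff(assign_stress_index(x)) >= 0))
})

test_that("calibration is exact on separable and degenerate instances", {
  cal <- calibrate_stress_intervals(c(10, 40, 70, 100, 150), 0:4)
  expect_equal(cal$match_rate, 1)
  expect_identical(assign_stress_index(c(10, 40, 70, 100, 150), cal$intervals), 0:4)

  # constant label: everything lands in one interval, rate 1
  cal2 <- calibrate_stress_intervals(seq(10, 100, length.out = 12), rep(2L, 12))
  expect_equal(cal2$match_rate, 1)
  expect_true(all(assign_stress_index(seq(10, 100, length.out = 12),
                                      cal2$intervals) == 2L))

  expect_error(calibrate_stress_intervals(rep(c(10, 20), 5), rep(0L, 10)),
               "distinct")
})

test_that("dynamic-programming calibration equals exhaustive search", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(8:50, 1)
    cpws <- round(runif(n, 5, 200), sample(0:1, 1))  # rounding creates ties
    morph <- sample(0:4, n, replace = TRUE,
                    prob = c(0.1, 0.2, 0.3, 0.25, 0.15))
    if (length(unique(cpws)) < 5) next
    cal <- calibrate_stress_intervals(cpws, morph)
    oracle <- oracle_calibrate(cpws, morph)
    expect_identical(cal$matched, as.integer(oracle$matched))
    # same boundary positions (cut l lies in the gap after block b[l])
    v <- sort(unique(cpws))
    expect_identical(findInterval(cal$intervals$cuts_kPa, v), oracle$boundaries)
    # the cuts achieve exactly the reported optimum
    ach <- agreement_rate(assign_stress_index(cpws, cal$intervals), morph)
    expect_identical(ach$matched, cal$matched)
  }
})

test_that("calibration dominates any fixed intervals and ignores slice order", {
  set.seed(123)
  cpws <- exp(rnorm(200, log(80), 0.6))
  morph <- pmin(4L, pmax(0L, round(2 + scale(log(cpws)) * 1.2 + rnorm(200, 0, 0.8))))
  morph <- as.integer(morph)
  cal <- calibrate_stress_intervals(cpws, morph)
  fixed <- agreement_rate(assign_stress_index(cpws), morph)
  expect_gte(cal$match_rate, fixed$rate)
  achieved <- agreement_rate(assign_stress_index(cpws, cal$intervals), morph)
  expect_equal(achieved$rate, cal$match_rate)

  perm <- sample(200)
  cal_p <- calibrate_stress_intervals(cpws[perm], morph[perm])
  expect_equal(cal_p$intervals$cuts_kPa, cal$intervals$cuts_kPa)
  expect_equal(cal_p$match_rate, cal$match_rate)
})

test_that("agreement rate counts exact matches", {
  a <- agreement_rate(c(1, 2, 3), c(1, 2, 4))
  expect_identical(a$matched, 2L)
  expect_identical(a$unmatched, 1L)
  expect_equal(a$rate, 2 / 3)
  expect_equal(agreement_rate(0:4, 0:4)$rate, 1)
  expect_equal(agreement_rate(rep(1L, 5), rep(2L, 5))$rate, 0)
  expect_error(agreement_rate(1:3, 1:4), "equal length")
})
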