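test_that("lq_bed reproduces closed-form anchors", {
  expect_equal(lq_bed(34.9, fractionation_scheme(3, 10)), 75.5,
               tolerance = 0.05 / 75.5)
  expect_equal(lq_bed(0, fractionation_scheme(5, 10)), 0)
  expect_equal(lq_bed(50, fractionation_scheme(5, 10)), 100)
  expect_error(lq_bed(-1, fractionation_scheme(5, 10)), ">= 0")
  expect_error(fractionation_scheme(0, 10), "positive integer")
  expect_error(fractionation_scheme(5, -1), "> 0")
})

test_that("BED dominates physical dose and is strictly increasing", {
  set.seed(21)
  scheme <- fractionation_scheme(5, 10)
  d <- sort(runif(200, 0.01, 80))
  bed <- lq_bed(d, scheme)
  expect_true(all(bed > d))
  expect_true(all(diff(bed) > 0))
})

test_that("bed_transform_dvh maps the axis and preserves invariants", {
  g <- dose_grid(array(40, c(3, 3, 3)))
  m <- structure_mask("PTV", array(TRUE, c(3, 3, 3)))
  dvh <- compute_cumulative_dvh(g, m, 0.05)
  scheme <- fractionation_scheme(5, 10)
  bed <- bed_transform_dvh(dvh, scheme)
  # uniform 40 Gy in 5 fractions -> 72 Gy BED plateau (one-bin tolerance)
  d50 <- dose_at_volume(dvh, 50)
  expect_equal(dose_at_volume(bed, 50), lq_bed(d50, scheme),
               tolerance = (lq_bed(d50 + 0.05, scheme) - lq_bed(d50, scheme)) /
                 lq_bed(d50, scheme))
  expect_equal(dose_at_volume(bed, 50), 72, tolerance = 0.2)
  expect_identical(bed$volume_fraction, dvh$volume_fraction)
  # alpha/beta -> infinity: BED axis approaches the physical axis
  near_id <- bed_transform_dvh(dvh, fractionation_scheme(5, 1e9))
  expect_equal(near_id$dose_edges, dvh$dose_edges, tolerance = 1e-6)
})

test_that("BED transform commutes with quantile extraction on random DVHs", {
  set.seed(33)
  scheme <- fractionation_scheme(5, 10)
  for (i in 1:15) {
    gm <- random_grid_mask()
    bw <- 0.05
    dvh <- compute_cumulative_dvh(gm$dose, gm$mask, bw)
    bed <- bed_transform_dvh(dvh, scheme)
    for (v in c(2, 50, 95, 98)) {
      d <- dose_at_volume(dvh, v)
      tol <- lq_bed(d + bw, scheme) - lq_bed(d, scheme)  # one bin, BED scale
      expect_equal(dose_at_volume(bed, v), lq_bed(d, scheme),
                   tolerance = tol + 1e-12)
    }
  }
})

test_that("tcp_logistic anchors, monotonicity, and limits", {
  params <- tcp_params()
  expect_identical(tcp_logistic(params$d50_bed_gy, params), 0.5)
  # independent evaluation of the logistic form at the worst-case BED
  d <- 72.6
  expect_equal(tcp_logistic(d, params), 1 / (1 + (75.5 / 72.6)^(4 / 1.22)))
  expect_equal(tcp_logistic(d, params), 0.468, tolerance = 2e-3)
  set.seed(14)
  d <- sort(runif(100, 1, 200))
  expect_true(all(diff(tcp_logistic(d, params)) > 0))
  expect_lt(tcp_logistic(1e-6, params), 1e-10)
  expect_gt(tcp_logistic(1e9, params), 1 - 1e-6)
  expect_error(tcp_logistic(0, params), "> 0")
  expect_error(tcp_params(-1, 1), "> 0")
})

test_that("tcp_logistic returns exactly 0.5 at D50 for random parameters", {
  set.seed(2)
  for (i in 1:100) {
    p <- tcp_params(runif(1, 10, 200), runif(1, 0.1, 5))
    expect_identical(tcp_logistic(p$d50_bed_gy, p), 0.5)
  }
})

test_that("invert_tcp is the exact inverse of tcp_logistic", {
  params <- tcp_params()
  expect_equal(invert_tcp(0.5, params), params$d50_bed_gy)
  expect_equal(invert_tcp(0.468, params), 72.6, tolerance = 1e-2 / 72.6)
  set.seed(8)
  p <- runif(1000, 0.01, 0.99)
  expect_equal(tcp_logistic(invert_tcp(p, params), params), p,
               tolerance = 1e-12)
  expect_error(invert_tcp(0, params), "strictly between")
  expect_error(invert_tcp(1, params), "strictly between")
})

test_that("tcp_from_dvh uses the configured coverage quantile", {
  scheme <- fractionation_scheme(5, 10)
  params <- tcp_params()
  # uniform plateau at the physical dose whose BED equals D50 -> TCP 0.5
  d50_phys <- (-1 + sqrt(1 + 4 * params$d50_bed_gy / (5 * 10))) / (2 / (5 * 10))
  g <- dose_grid(array(d50_phys, c(3, 3, 3)))
  m <- structure_mask("PTV", array(TRUE, c(3, 3, 3)))
  dvh <- compute_cumulative_dvh(g, m, 1e-4)
  expect_equal(tcp_from_dvh(dvh, scheme, params), 0.5, tolerance = 1e-3)

  # uniform down-scaling strictly lowers TCP
  g2 <- dose_grid(g$values * 0.95)
  dvh2 <- compute_cumulative_dvh(g2, m, 1e-4)
  expect_lt(tcp_from_dvh(dvh2, scheme, params), tcp_from_dvh(dvh, scheme, params))

  # two-point oracle: %dTCP from the lowered D95 matches direct evaluation
  d95 <- dose_at_volume(dvh, 95)
  d95_lo <- dose_at_volume(dvh2, 95)
  tcp_hi <- 1 / (1 + (params$d50_bed_gy / lq_bed(d95, scheme))^(4 / 1.22))
  tcp_lo <- 1 / (1 + (params$d50_bed_gy / lq_bed(d95_lo, scheme))^(4 / 1.22))
  expect_equal(percent_difference(tcp_from_dvh(dvh, scheme, params),
                                  tcp_from_dvh(dvh2, scheme, params)),
               100 * (tcp_hi - tcp_lo) / tcp_hi, tolerance = 1e-6)
})
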