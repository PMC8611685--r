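test_that("containers validate their invariants", {
  expect_error(dose_grid(matrix(1, 2, 2)), "3-D")
  expect_error(dose_grid(array(-1, c(2, 2, 2))), "non-negative")
  expect_error(dose_grid(array(Inf, c(2, 2, 2))), "finite")
  expect_error(dose_grid(array(1, c(2, 2, 2)), spacing_mm = c(1, 0, 1)),
               "spacing")
  expect_error(structure_mask("m", array(1, c(2, 2, 2))), "logical")
  expect_error(cumulative_dvh(c(0, 1), c(0.9, 0.5), 1), "zero dose")
  expect_error(cumulative_dvh(c(0, 1, 1), c(1, 0.5, 0.4), 1),
               "strictly increasing")
  expect_error(cumulative_dvh(c(0, 1, 2), c(1, 0.4, 0.5), 1), "non-monotone")
})

test_that("DVH of a uniform field is a step at the plateau dose", {
  g <- dose_grid(array(40, c(10, 1, 1)))
  m <- structure_mask("PTV", array(TRUE, c(10, 1, 1)))
  dvh <- compute_cumulative_dvh(g, m, bin_width_gy = 0.1)
  expect_equal(dvh$volume_fraction[dvh$dose_edges <= 40],
               rep(1, sum(dvh$dose_edges <= 40)))
  expect_equal(dvh$volume_fraction[dvh$dose_edges > 40],
               rep(0, sum(dvh$dose_edges > 40)))
  expect_equal(dvh$total_volume_cc, 10 * 2.5^3 / 1000)
})

test_that("two-voxel DVH matches the hand-counted fractions", {
  g <- dose_grid(array(c(10, 30), c(2, 1, 1)))
  m <- structure_mask("PTV", array(TRUE, c(2, 1, 1)))
  dvh <- compute_cumulative_dvh(g, m, bin_width_gy = 10)
  expect_equal(dvh$dose_edges, c(0, 10, 20, 30, 40))
  expect_equal(dvh$volume_fraction, c(1, 1, 0.5, 0.5, 0))
})

test_that("DVH engine equals the per-voxel counting oracle at every edge", {
  set.seed(42)
  for (i in 1:25) {
    gm <- random_grid_mask()
    bw <- sample(c(0.05, 0.1, 0.5, 2), 1)
    dvh <- compute_cumulative_dvh(gm$dose, gm$mask, bw)
    expect_identical(dvh$volume_fraction,
                     oracle_dvh_fractions(gm$dose, gm$mask, dvh$dose_edges))
  }
})

test_that("misaligned or empty inputs are refused", {
  g <- dose_grid(array(1, c(2, 2, 2)))
  m_bad <- structure_mask("m", array(TRUE, c(2, 2, 3)))
  m_empty <- structure_mask("m", array(FALSE, c(2, 2, 2)))
  expect_error(compute_cumulative_dvh(g, m_bad), "misaligned")
  expect_error(compute_cumulative_dvh(g, m_empty), "empty structure")
  expect_error(mean_dose(g, m_empty), "empty structure")
  m_off <- structure_mask("m", array(TRUE, c(2, 2, 2)), spacing_mm = 3)
  expect_error(mean_dose(g, m_off), "misaligned")
})

test_that("dose_at_volume inverts a piecewise-linear DVH exactly", {
  dvh <- cumulative_dvh(0:100, 1 - (0:100) / 100, total_volume_cc = 10)
  expect_equal(dose_at_volume(dvh, 95), 5)
  expect_equal(dose_at_volume(dvh, 2), 98)
  # interpolated inverse: vf(dose_at_volume(v)) = v/100 on a fine sweep
  for (v in c(0.5, 12.5, 33.3, 77.7, 99.5)) {
    d <- dose_at_volume(dvh, v)
    expect_equal(1 - d / 100, v / 100, tolerance = 1e-12)
  }
  expect_error(dose_at_volume(dvh, 0), "strictly between")
  expect_error(dose_at_volume(dvh, 100), "strictly between")
})

test_that("dose_at_volume is non-increasing in volume and capped at max dose", {
  set.seed(7)
  gm <- random_grid_mask()
  dvh <- compute_cumulative_dvh(gm$dose, gm$mask, 0.1)
  vols <- c(2, 20, 50, 80, 95, 98)
  doses <- vapply(vols, function(v) dose_at_volume(dvh, v), numeric(1))
  expect_true(all(diff(doses) <= 1e-12))
  # a DVH that never drops to the requested fraction returns the max dose
  plateau <- cumulative_dvh(c(0, 10, 20), c(1, 1, 0.9), 5)
  expect_equal(dose_at_volume(plateau, 50), 20)
})

test_that("mean_dose matches two-point and partition identities", {
  g <- dose_grid(array(c(10, 30), c(2, 1, 1)))
  m <- structure_mask("m", array(TRUE, c(2, 1, 1)))
  expect_equal(mean_dose(g, m), 20)
  set.seed(3)
  gm <- random_grid_mask()
  half <- array(FALSE, dim(gm$mask$values))
  half[1:3, , ] <- TRUE
  a <- structure_mask("a", gm$mask$values & half)
  b <- structure_mask("b", gm$mask$values & !half)
  if (any(a$values) && any(b$values)) {
    na <- sum(a$values); nb <- sum(b$values)
    expect_equal(mean_dose(gm$dose, gm$mask),
                 (na * mean_dose(gm$dose, a) + nb * mean_dose(gm$dose, b)) /
                   (na + nb))
  }
})

test_that("split_target forms a disjoint partition of the target", {
  set.seed(9)
  for (i in 1:10) {
    shape <- c(6L, 6L, 6L)
    ptv <- structure_mask("PTV", array(runif(216) < 0.5, shape))
    lung <- structure_mask("Lung", array(runif(216) < 0.5, shape))
    parts <- split_target(ptv, lung)
    expect_false(any(parts$ptv_lung$values & parts$ptv_soft$values))
    expect_identical(parts$ptv_lung$values | parts$ptv_soft$values,
                     ptv$values)
    expect_equal(sum(parts$ptv_lung$values) + sum(parts$ptv_soft$values),
                 sum(ptv$values))
  }
  # degenerate overlaps
  none <- structure_mask("Lung", array(FALSE, c(6L, 6L, 6L)))
  parts <- split_target(ptv, none)
  expect_false(any(parts$ptv_lung$values))
  expect_identical(parts$ptv_soft$values, ptv$values)
})

test_that("combine_dvhs satisfies identity and partition properties", {
  g <- dose_grid(array(c(10, 30), c(2, 1, 1)))
  m <- structure_mask("m", array(TRUE, c(2, 1, 1)))
  dvh <- compute_cumulative_dvh(g, m, 1)
  empty <- cumulative_dvh(c(0, 1), c(1, 0), total_volume_cc = 0)
  expect_identical(combine_dvhs(dvh, empty), dvh)
  same <- combine_dvhs(dvh, dvh)
  expect_equal(same$volume_fraction[match(dvh$dose_edges, same$dose_edges)],
               dvh$volume_fraction)
  expect_equal(same$total_volume_cc, 2 * dvh$total_volume_cc)
  expect_error(combine_dvhs(empty, empty), "zero combined volume")

  # partition identity on random grids: sub-DVHs recombine to the whole
  set.seed(11)
  for (i in 1:10) {
    gm <- random_grid_mask()
    half <- array(FALSE, dim(gm$mask$values))
    half[, 1:4, ] <- TRUE
    a <- structure_mask("a", gm$mask$values & half)
    b <- structure_mask("b", gm$mask$values & !half)
    if (!any(a$values) || !any(b$values)) next
    bw <- 0.1
    whole <- compute_cumulative_dvh(gm$dose, gm$mask, bw)
    comb <- combine_dvhs(compute_cumulative_dvh(gm$dose, a, bw),
                         compute_cumulative_dvh(gm$dose, b, bw))
    at <- resample_fractions(comb, whole$dose_edges)
    expect_lt(max(abs(at - whole$volume_fraction)), 1 / sum(gm$mask$values) + 1e-9)
    expect_equal(comb$total_volume_cc, whole$total_volume_cc)
  }
})

test_that("metric ordering D2 >= D95 >= D98 holds on generated phantoms", {
  phantom <- small_phantom()
  dose <- generate_reference_dose(phantom, 40, seed = 5)
  for (mask in list(phantom$ptv_mask)) {
    dvh <- compute_cumulative_dvh(dose, mask)
    m <- dose_metrics(dvh, mean_dose(dose, mask))
    expect_true(m$d2 >= m$d95)
    expect_true(m$d95 >= m$d98)
  }
})
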