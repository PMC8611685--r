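test_that("build_phantom hits the requested lung fraction", {
  # target fraction 0: PTV entirely in the liver half-space
  spec0 <- phantom_spec(c(40L, 20L, 20L), 2.5, interface_index = 20L,
                        ptv_radii_mm = c(10, 12, 12),
                        lung_fraction_target = 0)
  ph0 <- build_phantom(spec0)
  expect_equal(ph0$achieved_lung_fraction, 0)
  expect_false(any(ph0$ptv_mask$values & ph0$lung_mask$values))

  # spherical target asked to straddle symmetrically: fraction near 0.5
  spec5 <- phantom_spec(c(48L, 24L, 24L), 2.5, interface_index = 24L,
                        ptv_radii_mm = c(15, 15, 15),
                        lung_fraction_target = 0.5)
  ph5 <- build_phantom(spec5)
  expect_lt(abs(ph5$achieved_lung_fraction - 0.5), 0.05)

  # intermediate fractions across the configured range
  for (target in c(0.1, 0.25, 0.4, 0.6)) {
    spec <- phantom_spec(c(48L, 24L, 24L), 2.5, interface_index = 24L,
                         ptv_radii_mm = c(13, 11, 14),
                         lung_fraction_target = target)
    ph <- build_phantom(spec)
    expect_lt(abs(ph$achieved_lung_fraction - target), 0.05)
  }
})

test_that("rasterized ellipsoid volume approximates the analytic volume", {
  radii <- c(14, 16, 13)                  # >= 5 voxels at 2.5 mm
  spec <- phantom_spec(c(48L, 28L, 28L), 2.5, interface_index = 24L,
                       ptv_radii_mm = radii, lung_fraction_target = 0.3)
  ph <- build_phantom(spec)
  analytic_cc <- 4 / 3 * pi * prod(radii) / 1000
  expect_lt(abs(mask_volume_cc(ph$ptv_mask) - analytic_cc) / analytic_cc, 0.05)
})

test_that("degenerate geometry requests are refused", {
  expect_error(phantom_spec(c(10L, 10L, 10L), 2.5, interface_index = 12L,
                            ptv_radii_mm = c(5, 5, 5)),
               "interface_index")
  # radii larger than the grid: target cannot fit
  spec <- phantom_spec(c(16L, 10L, 10L), 2.5, interface_index = 8L,
                       ptv_radii_mm = c(30, 5, 5), lung_fraction_target = 0.3)
  expect_error(build_phantom(spec), "fit")
})

test_that("reference dose meets coverage and hotspot constraints", {
  phantom <- small_phantom()
  rx <- 40
  dose <- generate_reference_dose(phantom, rx, seed = 9)
  in_ptv <- dose$values[phantom$ptv_mask$values]
  expect_gte(mean(in_ptv >= rx), 0.95)
  expect_lte(max(dose$values), 1.05 * rx)
  dvh <- compute_cumulative_dvh(dose, phantom$ptv_mask)
  expect_gte(dose_at_volume(dvh, 95), rx)
  # identical spec + seed reproduces the grid bit-identically
  expect_identical(dose$values,
                   generate_reference_dose(phantom, rx, seed = 9)$values)
  expect_false(identical(dose$values,
                         generate_reference_dose(phantom, rx, seed = 10)$values))
})

test_that("identity perturbation model returns the reference dose", {
  phantom <- small_phantom()
  dose <- generate_reference_dose(phantom, 40, seed = 2)
  ident <- perturbation_model(1, 0, 0, 0, noise_sd = 0)
  out <- apply_algorithm_perturbation(dose, phantom, ident, seed = 3)
  expect_identical(out$values, dose$values)
})

test_that("lung deficit lowers lung-region dose below soft-tissue dose", {
  phantom <- small_phantom()
  dose <- generate_reference_dose(phantom, 40, seed = 4)
  parts <- split_target(phantom$ptv_mask, phantom$lung_mask)
  for (seed in 1:5) {
    pert <- apply_algorithm_perturbation(dose, phantom,
                                         perturbation_model_dm(), seed)
    r_lung <- mean_dose(pert, parts$ptv_lung) / mean_dose(dose, parts$ptv_lung)
    r_soft <- mean_dose(pert, parts$ptv_soft) / mean_dose(dose, parts$ptv_soft)
    expect_lt(r_lung, r_soft)
    expect_gt(min(pert$values[dose$values > 0]), 0)
  }
})

test_that("simulate_cohort is deterministic and patient-stable", {
  config <- cohort_config(n_patients = 2, ptv_volume_range_cc = c(15.4, 40))
  a <- simulate_cohort(config, seed = 5)
  b <- simulate_cohort(config, seed = 5)
  expect_equal(length(a), 2L)
  expect_identical(a[[1L]]$doses$AAA$values, b[[1L]]$doses$AAA$values)
  expect_identical(a[[2L]]$doses$AXB_Dm$values, b[[2L]]$doses$AXB_Dm$values)
  expect_identical(a[[1L]]$prescription_gy, b[[1L]]$prescription_gy)

  # adding a patient leaves earlier patients untouched (counter-based seeds)
  config3 <- cohort_config(n_patients = 3, ptv_volume_range_cc = c(15.4, 40))
  c3 <- simulate_cohort(config3, seed = 5)
  expect_identical(a[[2L]]$doses$AXB_Dw$values, c3[[2L]]$doses$AXB_Dw$values)

  # a different seed changes the cohort
  d <- simulate_cohort(config, seed = 6)
  expect_false(identical(a[[1L]]$doses$AAA$values, d[[1L]]$doses$AAA$values))
})

test_that("single-patient cohort carries a complete paired triple", {
  co <- simulate_cohort(cohort_config(n_patients = 1,
                                      ptv_volume_range_cc = c(15.4, 30)),
                        seed = 3)
  p <- co[[1L]]
  expect_named(p$doses, c("AAA", "AXB_Dm", "AXB_Dw"))
  expect_true(all(vapply(p$doses, inherits, logical(1), "dose_grid")))
  expect_true(p$achieved_lung_fraction >= 0 && p$achieved_lung_fraction < 1)
  expect_gte(mask_volume_cc(p$phantom$ptv_mask), 10)
})
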