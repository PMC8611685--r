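# Brute-force per-voxel counting oracle for the cumulative DVH: evaluates
# the defining count at every edge independently of the package's
# findInterval-based path.
oracle_dvh_fractions <- function(dose, mask, edges) {
  doses <- dose$values[mask$values]
  vapply(edges, function(d) sum(doses >= d) / length(doses), numeric(1))
}

# Random dose grid + non-empty mask on a small lattice.
random_grid_mask <- function(shape = c(6L, 7L, 8L), max_dose = 50) {
  vals <- array(stats::runif(prod(shape), 0, max_dose), shape)
  repeat {
    m <- array(stats::runif(prod(shape)) < 0.4, shape)
    if (any(m)) break
  }
  list(dose = dose_grid(vals), mask = structure_mask("roi", m))
}

# Test-side piecewise-linear resampling of a cumulative curve.
resample_fractions <- function(dvh, edges) {
  stats::approx(dvh$dose_edges, dvh$volume_fraction, xout = edges,
                rule = 2, ties = "ordered")$y
}

# Small interface phantom used across property tests.
small_phantom <- function(lung_fraction = 0.35, radii = c(12, 14, 10)) {
  spec <- phantom_spec(grid_shape = c(40L, 24L, 24L), spacing_mm = 2.5,
                       interface_index = 20L, ptv_radii_mm = radii,
                       lung_fraction_target = lung_fraction)
  build_phantom(spec)
}

# Hand-built 3-patient toy cohort in long format (values chosen so the
# summary can be checked against a spreadsheet-style manual calculation).
toy_records <- function() {
  vals <- rbind(
    c(40.0, 39.0, 39.5),
    c(42.0, 41.5, 41.8),
    c(38.0, 36.5, 37.0))
  cohort_records(
    patient_id = rep(c("A", "B", "C"), each = 3L),
    region = "PTV_Whole",
    metric = "D95",
    arm = rep(c("AAA", "AXB_Dm", "AXB_Dw"), times = 3L),
    value = as.vector(t(vals)))
}

# Tiny run_config for fast end-to-end tests: few small patients.
tiny_config <- function(n_patients = 2, seed = 11) {
  config <- default_run_config()
  config$synthetic$n_patients <- n_patients
  config$synthetic$ptv_volume_range_cc <- c(15.4, 60)
  config$synthetic$seed <- seed
  config
}
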