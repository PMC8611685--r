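# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards, so cohort generation never perturbs (and is
# never perturbed by) the session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Counter-based per-patient sub-seed: patient i's stream depends only on
# (seed, i, stage), so adding patients to a cohort never changes earlier
# patients. Kept below 2^31 - 1.
derive_seed <- function(seed, patient, stage = 0L) {
  as.integer((as.double(seed) * 48271 + patient * 16807 + stage * 69621) %%
               2147483629 + 1)
}

# Truncated-normal draw on [lo, hi] by inverse-CDF, so boundary atoms have
# probability zero (a deficit amplitude of exactly 0 would void the
# lung-vs-soft ordering invariant).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Phantom geometry specification
#'
#' Describes a two-compartment slab phantom: a low-density (lung) half-space
#' above a planar interface and a unit-density (liver/soft-tissue)
#' half-space below it, with an ellipsoidal target straddling the interface.
#' Lung occupies voxels with z-index `>= interface_index` (0-based).
#'
#' @param grid_shape integer voxel counts per (z, y, x) axis.
#' @param spacing_mm voxel size in mm (scalar or length 3, default 2.5).
#' @param interface_index 0-based z index of the first lung voxel plane.
#' @param ptv_radii_mm ellipsoid semi-axes (z, y, x) in mm.
#' @param ptv_center_yx_mm transverse (y, x) centre in mm; defaults to the
#'   grid centre. The z centre is solved for by [build_phantom()].
#' @param lung_fraction_target intended fraction of target volume inside
#'   lung, in `[0, 1)`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing_mm = 2.5, interface_index,
                         ptv_radii_mm, ptv_center_yx_mm = NULL,
                         lung_fraction_target = 0.3) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(all(spacing_mm > 0), length(ptv_radii_mm) == 3L,
            all(ptv_radii_mm > 0))
  if (lung_fraction_target < 0 || lung_fraction_target >= 1)
    stop("lung_fraction_target must lie in [0, 1)", call. = FALSE)
  interface_index <- as.integer(interface_index)
  if (interface_index < 1L || interface_index >= grid_shape[1L])
    stop("interface_index must split the grid into two non-empty halves",
         call. = FALSE)
  if (is.null(ptv_center_yx_mm))
    ptv_center_yx_mm <- (grid_shape[2:3] - 1) / 2 * spacing_mm[2:3]
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 interface_index = interface_index,
                 ptv_radii_mm = as.numeric(ptv_radii_mm),
                 ptv_center_yx_mm = as.numeric(ptv_center_yx_mm),
                 lung_fraction_target = lung_fraction_target),
            class = "phantom_spec")
}

#' Per-arm dose-discrepancy model
#'
#' Parameterises the multiplicative discrepancy field of a
#' transport-accurate ("AXB-like") recalculation relative to the reference
#' ("AAA-like") dose: a per-patient global factor `s` in soft tissue and an
#' additional dose deficit in lung that is maximal at the tissue interface
#' and decays exponentially with depth into lung (rebuild-up scale
#' `deficit_length_mm`), i.e. `f = s * (1 - A * exp(-depth/lambda))` in lung.
#'
#' @param soft_ratio_mean,soft_ratio_sd per-patient mean and SD of the soft
#'   tissue multiplicative factor `s`.
#' @param lung_deficit_amplitude_mean,lung_deficit_amplitude_sd per-patient
#'   mean and SD of the peak fractional deficit `A`, truncated to
#'   `[0, 0.3]`.
#' @param deficit_length_mm exponential depth scale of the deficit (default
#'   15 mm).
#' @param noise_sd SD of voxel-level multiplicative Gaussian noise applied
#'   last (default 0.005).
#' @return An object of class `perturbation_model`.
#' @seealso [perturbation_model_dm()], [perturbation_model_dw()] for the
#'   shipped dose-to-medium and dose-to-water calibrations.
#' @export
perturbation_model <- function(soft_ratio_mean, soft_ratio_sd,
                               lung_deficit_amplitude_mean,
                               lung_deficit_amplitude_sd,
                               deficit_length_mm = 15, noise_sd = 0.005) {
  stopifnot(soft_ratio_mean > 0, soft_ratio_sd >= 0,
            lung_deficit_amplitude_sd >= 0, deficit_length_mm > 0,
            noise_sd >= 0)
  structure(list(soft_ratio_mean = soft_ratio_mean,
                 soft_ratio_sd = soft_ratio_sd,
                 lung_deficit_amplitude_mean = lung_deficit_amplitude_mean,
                 lung_deficit_amplitude_sd = lung_deficit_amplitude_sd,
                 deficit_length_mm = deficit_length_mm,
                 noise_sd = noise_sd),
            class = "perturbation_model")
}

#' @rdname perturbation_model
#' @details The shipped defaults are calibrated so that a default cohort
#'   lands near published per-region ratio summaries (soft-tissue Dmean
#'   ratio about 98.5% for dose-to-medium, lung D98% ratio in the low 90s
#'   with several-percent spread); this is a calibration of the generator,
#'   not a validation against patient data.
#' @export
perturbation_model_dm <- function() {
  perturbation_model(soft_ratio_mean = 0.985, soft_ratio_sd = 0.002,
                     lung_deficit_amplitude_mean = 0.045,
                     lung_deficit_amplitude_sd = 0.045)
}

#' @rdname perturbation_model
#' @export
perturbation_model_dw <- function() {
  perturbation_model(soft_ratio_mean = 0.998, soft_ratio_sd = 0.002,
                     lung_deficit_amplitude_mean = 0.060,
                     lung_deficit_amplitude_sd = 0.045)
}

#' Cohort-level simulation configuration
#'
#' @param n_patients number of phantoms (default 23).
#' @param prescription_pool_gy allowed 5-fraction prescriptions in Gy
#'   (default 27.5, 30, 35, 40, 45, 50; must lie within `[27.5, 50]`).
#' @param ptv_volume_range_cc range of target volumes, sampled log-uniformly
#'   (default 15.4-664 cc).
#' @param lung_fraction_range range of the target's lung-volume fraction,
#'   sampled uniformly (default 0.05-0.6).
#' @param spacing_mm isotropic voxel size in mm (default 2.5).
#' @param model_dm,model_dw [perturbation_model()]s for the dose-to-medium
#'   and dose-to-water arms.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 23,
                          prescription_pool_gy = c(27.5, 30, 35, 40, 45, 50),
                          ptv_volume_range_cc = c(15.4, 664),
                          lung_fraction_range = c(0.05, 0.6),
                          spacing_mm = 2.5,
                          model_dm = perturbation_model_dm(),
                          model_dw = perturbation_model_dw()) {
  stopifnot(n_patients >= 1,
            all(prescription_pool_gy >= 27.5), all(prescription_pool_gy <= 50),
            length(ptv_volume_range_cc) == 2L,
            ptv_volume_range_cc[1L] > 0,
            diff(ptv_volume_range_cc) >= 0,
            length(lung_fraction_range) == 2L,
            lung_fraction_range[1L] >= 0, lung_fraction_range[2L] < 1,
            spacing_mm > 0,
            inherits(model_dm, "perturbation_model"),
            inherits(model_dw, "perturbation_model"))
  structure(list(n_patients = as.integer(n_patients),
                 prescription_pool_gy = as.numeric(prescription_pool_gy),
                 ptv_volume_range_cc = as.numeric(ptv_volume_range_cc),
                 lung_fraction_range = as.numeric(lung_fraction_range),
                 spacing_mm = as.numeric(spacing_mm),
                 model_dm = model_dm, model_dw = model_dw),
            class = "cohort_config")
}

# Axis coordinate vectors (mm) of a spec's lattice, and the physical z of
# the lung-liver interface (boundary between voxel planes).
axis_coords <- function(grid_shape, spacing_mm) {
  lapply(1:3, function(a) (seq_len(grid_shape[a]) - 1) * spacing_mm[a])
}

interface_z_mm <- function(spec) {
  (spec$interface_index - 0.5) * spec$spacing_mm[1L]
}

# Rasterize the ellipsoid centred at (cz, cy, cx) mm; returns logical array.
rasterize_ellipsoid <- function(coords, center_mm, radii_mm) {
  az <- ((coords[[1L]] - center_mm[1L]) / radii_mm[1L])^2
  ay <- ((coords[[2L]] - center_mm[2L]) / radii_mm[2L])^2
  ax <- ((coords[[3L]] - center_mm[3L]) / radii_mm[3L])^2
  outer(outer(az, ay, "+"), ax, "+") <= 1
}

#' Build a two-compartment interface phantom
#'
#' Rasterizes the target ellipsoid on the lattice and solves for its z
#' centre (bisection along the interface normal) so that the achieved
#' fraction of target voxels inside the lung half-space is within 0.05 of
#' `lung_fraction_target`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `lung_mask` and `ptv_mask` ([structure_mask()]s),
#'   `achieved_lung_fraction`, and `ptv_center_mm`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  coords <- axis_coords(spec$grid_shape, spec$spacing_mm)
  zi <- interface_z_mm(spec)
  rz <- spec$ptv_radii_mm[1L]
  lung_vals <- array(FALSE, spec$grid_shape)
  lung_vals[(spec$interface_index + 1L):spec$grid_shape[1L], , ] <- TRUE
  lung <- structure_mask("Lung", lung_vals, spec$spacing_mm)

  frac_at <- function(cz) {
    ptv <- rasterize_ellipsoid(coords, c(cz, spec$ptv_center_yx_mm),
                               spec$ptv_radii_mm)
    n <- sum(ptv)
    if (n == 0L) return(NA_real_)
    sum(ptv & lung_vals) / n
  }
  zmax <- max(coords[[1L]])
  lo <- rz; hi <- zmax - rz          # centre range keeping the PTV on-grid
  if (lo > hi)
    stop("target does not fit inside the grid along z", call. = FALSE)
  # clamp so the PTV always overlaps liver (fraction < 1 required)
  f_lo <- frac_at(lo); f_hi <- frac_at(hi)
  target <- spec$lung_fraction_target
  if (is.na(f_lo) || is.na(f_hi))
    stop("target radii too small for the lattice", call. = FALSE)
  if (target < min(f_lo, f_hi) - 0.05 || target > max(f_lo, f_hi) + 0.05)
    stop("unreachable lung fraction for the given radii/grid", call. = FALSE)
  best_cz <- lo; best_err <- abs(f_lo - target)
  if (abs(f_hi - target) < best_err) { best_cz <- hi; best_err <- abs(f_hi - target) }
  a <- lo; b <- hi; fa <- f_lo
  for (it in seq_len(60L)) {
    mid <- (a + b) / 2
    fm <- frac_at(mid)
    if (abs(fm - target) < best_err) { best_cz <- mid; best_err <- abs(fm - target) }
    if (best_err < 5e-4) break
    if ((fm - target) * (fa - target) <= 0) b <- mid else { a <- mid; fa <- fm }
  }
  if (best_err > 0.05)
    stop("unreachable lung fraction for the given radii/grid", call. = FALSE)
  center <- c(best_cz, spec$ptv_center_yx_mm)
  ptv_vals <- rasterize_ellipsoid(coords, center, spec$ptv_radii_mm)
  list(lung_mask = lung,
       ptv_mask = structure_mask("PTV_Whole", ptv_vals, spec$spacing_mm),
       achieved_lung_fraction = sum(ptv_vals & lung_vals) / sum(ptv_vals),
       ptv_center_mm = center, spec = spec)
}

#' Reference ("AAA-like") dose field for a phantom
#'
#' A smooth plan-shaped field: a plateau of about 1.02-1.04 times the
#' prescription inside the target with low-amplitude smooth modulation, and
#' a sigmoidal falloff outside the target surface reaching 50% of the
#' plateau at `penumbra_mm`. By construction at least 95% of the target
#' volume receives the prescription and the global maximum stays below
#' 1.05 times the prescription; both are verified and violations raise
#' errors.
#'
#' @param phantom result of [build_phantom()].
#' @param prescription_gy prescription dose in Gy.
#' @param seed integer seed for the smooth modulation draw.
#' @param plateau central plateau as a fraction of prescription (default
#'   1.03).
#' @param mod_amplitude amplitude of the smooth intra-target modulation as a
#'   fraction of prescription (default 0.008).
#' @param penumbra_mm distance outside the target surface at which the dose
#'   falls to 50% (default 8).
#' @return A [dose_grid()].
#' @export
generate_reference_dose <- function(phantom, prescription_gy, seed,
                                    plateau = 1.03, mod_amplitude = 0.008,
                                    penumbra_mm = 8) {
  spec <- phantom$spec
  stopifnot(prescription_gy > 0, penumbra_mm > 0)
  coords <- axis_coords(spec$grid_shape, spec$spacing_mm)
  az <- ((coords[[1L]] - phantom$ptv_center_mm[1L]) / spec$ptv_radii_mm[1L])^2
  ay <- ((coords[[2L]] - phantom$ptv_center_mm[2L]) / spec$ptv_radii_mm[2L])^2
  ax <- ((coords[[3L]] - phantom$ptv_center_mm[3L]) / spec$ptv_radii_mm[3L])^2
  r <- sqrt(outer(outer(az, ay, "+"), ax, "+"))
  r_eff <- prod(spec$ptv_radii_mm)^(1 / 3)
  s_mm <- (r - 1) * r_eff             # approx. signed distance to surface
  g <- 1 / (1 + exp((s_mm - penumbra_mm) / (penumbra_mm / 4)))
  mod <- with_seed(seed, {
    ph <- stats::runif(6, 0, 2 * pi)
    ext <- spec$grid_shape * spec$spacing_mm
    wz <- cos(2 * pi * coords[[1L]] / ext[1L] + ph[1L]) +
      0.5 * cos(4 * pi * coords[[1L]] / ext[1L] + ph[2L])
    wy <- cos(2 * pi * coords[[2L]] / ext[2L] + ph[3L]) +
      0.5 * cos(4 * pi * coords[[2L]] / ext[2L] + ph[4L])
    wx <- cos(2 * pi * coords[[3L]] / ext[3L] + ph[5L]) +
      0.5 * cos(4 * pi * coords[[3L]] / ext[3L] + ph[6L])
    field <- outer(outer(wz, wy, "+"), wx, "+")
    field / max(abs(field)) * mod_amplitude
  })
  dose <- prescription_gy * pmin(plateau + mod, 1.0499) * g
  grid <- dose_grid(dose, spec$spacing_mm)
  in_ptv <- phantom$ptv_mask$values
  coverage <- sum(dose[in_ptv] >= prescription_gy) / sum(in_ptv)
  if (coverage < 0.95)
    stop(sprintf("coverage constraint unsatisfiable: V(prescription) = %.1f%%",
                 100 * coverage), call. = FALSE)
  if (max(dose) > 1.05 * prescription_gy)
    stop("maximum dose exceeds 105% of prescription", call. = FALSE)
  grid
}

#' Apply an algorithm-discrepancy perturbation to a reference dose
#'
#' Multiplies the reference field by `s` in soft tissue and by
#' `s * (1 - A * exp(-depth_into_lung/lambda))` in lung, with the
#' per-patient factors `s ~ Normal(soft_ratio_mean, soft_ratio_sd)` and
#' `A ~ Normal(amplitude mean, sd)` truncated to `[0, 0.3]`; voxel-level
#' multiplicative noise is applied last.
#'
#' @param dose reference [dose_grid()].
#' @param phantom result of [build_phantom()] on the same lattice.
#' @param model a [perturbation_model()].
#' @param seed integer seed for the per-patient and voxel draws.
#' @return A perturbed [dose_grid()] (strictly positive wherever the
#'   reference is positive).
#' @export
apply_algorithm_perturbation <- function(dose, phantom, model, seed) {
  stopifnot(inherits(dose, "dose_grid"), inherits(model, "perturbation_model"))
  spec <- phantom$spec
  check_aligned(dose, phantom$lung_mask)
  with_seed(seed, {
    s <- stats::rnorm(1, model$soft_ratio_mean, model$soft_ratio_sd)
    amp <- rtrunc_norm(1, model$lung_deficit_amplitude_mean,
                       model$lung_deficit_amplitude_sd, 0, 0.3)
    zc <- (seq_len(spec$grid_shape[1L]) - 1) * spec$spacing_mm[1L]
    depth <- pmax(zc - interface_z_mm(spec), 0)   # mm into lung, 0 in liver
    fz <- ifelse(zc > interface_z_mm(spec),
                 s * (1 - amp * exp(-depth / model$deficit_length_mm)), s)
    factor <- array(fz, spec$grid_shape)          # constant over y, x planes
    if (model$noise_sd > 0)
      factor <- factor * stats::rnorm(length(factor), 1, model$noise_sd)
    if (min(factor) <= 0)
      stop("perturbation factor field is non-positive", call. = FALSE)
    dose_grid(dose$values * factor, dose$spacing_mm, dose$origin_mm)
  })
}

#' Simulate a paired-algorithm phantom cohort
#'
#' Draws `n_patients` independent phantoms (volumes log-uniform in the
#' configured range, lung fractions uniform, prescriptions from the
#' discrete pool), builds the reference ("AAA") dose for each, and applies
#' the dose-to-medium and dose-to-water discrepancy models. Each patient's
#' random stream is derived from `(seed, patient index)` by a counter-based
#' scheme, so the cohort is a pure function of `(config, seed)` and adding
#' patients does not change earlier ones.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @return A list of class `synthetic_cohort`; each element has
#'   `patient_id`, `phantom`, `prescription_gy`, `doses` (named list
#'   `AAA`, `AXB_Dm`, `AXB_Dw`), `achieved_lung_fraction`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  patients <- lapply(seq_len(config$n_patients), function(i) {
    geom_seed <- derive_seed(seed, i, 1L)
    draw <- with_seed(geom_seed, {
      vol <- exp(stats::runif(1, log(config$ptv_volume_range_cc[1L]),
                              log(config$ptv_volume_range_cc[2L])))
      lf <- stats::runif(1, config$lung_fraction_range[1L],
                         config$lung_fraction_range[2L])
      rx <- config$prescription_pool_gy[
        sample.int(length(config$prescription_pool_gy), 1L)]
      aniso <- stats::runif(3, 0.75, 1.3)
      list(vol = vol, lf = lf, rx = rx, aniso = aniso / prod(aniso)^(1 / 3))
    })
    r0 <- (3 * draw$vol * 1000 / (4 * pi))^(1 / 3)  # cc -> mm^3
    radii <- pmax(r0 * draw$aniso, 2 * config$spacing_mm)
    sp <- config$spacing_mm
    pad <- 15                                        # mm margin per side
    nz <- ceiling((4 * radii[1L] + 2 * pad) / sp) + 1L
    ny <- ceiling((2 * radii[2L] + 2 * pad) / sp) + 1L
    nx <- ceiling((2 * radii[3L] + 2 * pad) / sp) + 1L
    spec <- phantom_spec(grid_shape = c(nz, ny, nx), spacing_mm = sp,
                         interface_index = nz %/% 2L,
                         ptv_radii_mm = radii,
                         lung_fraction_target = draw$lf)
    phantom <- build_phantom(spec)
    ref <- generate_reference_dose(phantom, draw$rx,
                                   seed = derive_seed(seed, i, 2L))
    dm <- apply_algorithm_perturbation(ref, phantom, config$model_dm,
                                       seed = derive_seed(seed, i, 3L))
    dw <- apply_algorithm_perturbation(ref, phantom, config$model_dw,
                                       seed = derive_seed(seed, i, 4L))
    list(patient_id = sprintf("P%02d", i), phantom = phantom,
         prescription_gy = draw$rx,
         doses = list(AAA = ref, AXB_Dm = dm, AXB_Dw = dw),
         achieved_lung_fraction = phantom$achieved_lung_fraction,
         seed = geom_seed)
  })
  structure(patients, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  vols <- vapply(x, function(p) mask_volume_cc(p$phantom$ptv_mask), numeric(1))
  cat(sprintf("<synthetic_cohort> %d patients, PTV %.1f-%.1f cc\n",
              length(x), min(vols), max(vols)))
  invisible(x)
}
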