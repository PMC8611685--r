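#' Construct a 3-D absorbed-dose grid
#'
#' A `dose_grid` is a 3-D scalar field of absorbed dose in Gy on a regular
#' lattice. The axis order convention is `(z, y, x)` with 0-based physical
#' indexing: the physical position of voxel `(i, j, k)` (0-based) is
#' `origin + c(i, j, k) * spacing`, i.e. `origin` is the centre of the first
#' voxel.
#'
#' @param values numeric 3-D array of dose in Gy; all finite and `>= 0`.
#' @param spacing_mm numeric length-3 voxel size in mm per axis (z, y, x);
#'   all `> 0`. A scalar is recycled.
#' @param origin_mm numeric length-3 physical coordinate (mm) of the first
#'   voxel centre. Defaults to the origin.
#' @return An object of class `dose_grid` with fields `values`, `spacing_mm`,
#'   `origin_mm`.
#' @examples
#' g <- dose_grid(array(40, c(4, 4, 4)), spacing_mm = 2.5)
#' voxel_volume_cc(g)
#' @export
dose_grid <- function(values, spacing_mm = 2.5, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("dose values must be a 3-D array", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("every grid axis must have length >= 1", call. = FALSE)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("dose values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("dose values must be non-negative", call. = FALSE)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || !all(is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive finite numbers", call. = FALSE)
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || !all(is.finite(origin_mm)))
    stop("origin_mm must be 3 finite numbers", call. = FALSE)
  structure(list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "dose_grid")
}

#' Construct a binary structure mask on a grid lattice
#'
#' @param name label of the structure (e.g. `"PTV_Whole"`, `"Lung"`).
#' @param values logical 3-D array, `TRUE` inside the structure. Must share
#'   its lattice with the associated [dose_grid()].
#' @param spacing_mm voxel size in mm per (z, y, x) axis; scalar recycled.
#' @param origin_mm physical coordinate of the first voxel centre.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, values, spacing_mm = 2.5, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("mask values must be a 3-D array", call. = FALSE)
  if (!is.logical(values))
    stop("mask values must be logical", call. = FALSE)
  if (anyNA(values))
    stop("mask values must not contain NA", call. = FALSE)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  structure(list(name = as.character(name)[1L], values = values,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "structure_mask")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels (z,y,x), spacing %s mm, dose %.3f-%.3f Gy\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d of %d voxels (%.2f cc)\n",
              x$name, sum(x$values), length(x$values), mask_volume_cc(x)))
  invisible(x)
}

#' Voxel volume of a grid or mask, in cubic centimetres
#' @param x a `dose_grid` or `structure_mask`.
#' @return Volume of one voxel in cc.
#' @export
voxel_volume_cc <- function(x) prod(x$spacing_mm) / 1000

#' Absolute volume of a structure mask in cubic centimetres
#' @param mask a `structure_mask`.
#' @return Total structure volume in cc (voxel count times voxel volume).
#' @export
mask_volume_cc <- function(mask) sum(mask$values) * voxel_volume_cc(mask)

# Refuse silently resampling between mismatched lattices: metrics at a
# 2.5 mm grid are sensitive to resampling, so alignment is a hard precondition.
check_aligned <- function(grid, mask) {
  if (!identical(dim(grid$values), dim(mask$values)))
    stop("grid/mask misaligned", call. = FALSE)
  if (!isTRUE(all.equal(grid$spacing_mm, mask$spacing_mm, tolerance = 1e-9)) ||
      !isTRUE(all.equal(grid$origin_mm, mask$origin_mm, tolerance = 1e-9)))
    stop("grid/mask misaligned", call. = FALSE)
  invisible(TRUE)
}

check_masks_aligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("grid/mask misaligned", call. = FALSE)
  invisible(TRUE)
}

#' Mean absorbed dose over a structure
#'
#' @param dose a [dose_grid()].
#' @param mask an aligned, non-empty [structure_mask()].
#' @return Arithmetic mean dose over the masked voxels, in Gy.
#' @export
mean_dose <- function(dose, mask) {
  check_aligned(dose, mask)
  if (!any(mask$values)) stop("empty structure", call. = FALSE)
  mean(dose$values[mask$values])
}

#' Split a target volume by tissue membership
#'
#' Splits a PTV into the part inside a (low-density) tissue such as lung and
#' the complementary part in soft tissue. The two parts are disjoint and
#' their union is the original target.
#'
#' @param ptv target [structure_mask()].
#' @param lung tissue [structure_mask()] on the same lattice.
#' @return A list with elements `ptv_lung` (`ptv AND lung`) and `ptv_soft`
#'   (`ptv AND NOT lung`), named `"PTV_Lung"` and `"PTV_SoftTissue"`.
#' @export
split_target <- function(ptv, lung) {
  check_masks_aligned(ptv, lung)
  list(
    ptv_lung = structure_mask("PTV_Lung", ptv$values & lung$values,
                              ptv$spacing_mm, ptv$origin_mm),
    ptv_soft = structure_mask("PTV_SoftTissue", ptv$values & !lung$values,
                              ptv$spacing_mm, ptv$origin_mm)
  )
}
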