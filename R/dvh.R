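#' Construct a cumulative dose-volume histogram
#'
#' The cumulative DVH tabulates, at ascending dose values starting at 0 Gy,
#' the fraction of the structure volume receiving at least that dose. It is
#' the substrate of every dose metric and of BED conversion.
#'
#' @param dose_edges ascending numeric dose values in Gy, first edge 0.
#' @param volume_fraction non-increasing fractions in `[0, 1]`; must be 1 at
#'   dose 0 (within 1e-9).
#' @param total_volume_cc absolute structure volume in cc (`> 0`).
#' @param structure structure label carried along for reporting.
#' @return An object of class `cumulative_dvh`.
#' @export
cumulative_dvh <- function(dose_edges, volume_fraction, total_volume_cc,
                           structure = "structure") {
  dose_edges <- as.numeric(dose_edges)
  volume_fraction <- as.numeric(volume_fraction)
  if (length(dose_edges) != length(volume_fraction) || length(dose_edges) < 1L)
    stop("dose_edges and volume_fraction must have equal positive length",
         call. = FALSE)
  if (!all(is.finite(dose_edges)) || !all(is.finite(volume_fraction)))
    stop("DVH values must be finite", call. = FALSE)
  if (abs(dose_edges[1L]) > 1e-12)
    stop("first dose edge must be 0", call. = FALSE)
  if (length(dose_edges) > 1L && any(diff(dose_edges) <= 0))
    stop("dose edges must be strictly increasing", call. = FALSE)
  if (abs(volume_fraction[1L] - 1) > 1e-9)
    stop("volume fraction at zero dose must be 1", call. = FALSE)
  if (any(diff(volume_fraction) > 1e-12))
    stop("non-monotone DVH", call. = FALSE)
  if (volume_fraction[length(volume_fraction)] < -1e-12 ||
      any(volume_fraction > 1 + 1e-9))
    stop("volume fractions must lie in [0, 1]", call. = FALSE)
  if (!is.finite(total_volume_cc) || total_volume_cc < 0)
    stop("total_volume_cc must be non-negative", call. = FALSE)
  structure(list(dose_edges = dose_edges,
                 volume_fraction = pmin(pmax(volume_fraction, 0), 1),
                 total_volume_cc = as.numeric(total_volume_cc),
                 structure = as.character(structure)[1L]),
            class = "cumulative_dvh")
}

#' @export
print.cumulative_dvh <- function(x, ...) {
  cat(sprintf("<cumulative_dvh> '%s': %.2f cc, %d edges, 0-%.3f Gy\n",
              x$structure, x$total_volume_cc, length(x$dose_edges),
              max(x$dose_edges)))
  invisible(x)
}

#' Cumulative DVH of a structure on a dose grid
#'
#' Evaluates, at every bin edge `d` of a regular dose axis, the fraction of
#' masked voxels whose dose is `>= d` (whole-voxel membership, no
#' partial-volume weighting). The axis starts at 0 and extends one bin past
#' the structure maximum so that the curve reaches 0.
#'
#' @param dose a [dose_grid()].
#' @param mask an aligned, non-empty [structure_mask()].
#' @param bin_width_gy dose bin width in Gy (default 0.05).
#' @return A [cumulative_dvh()].
#' @examples
#' g <- dose_grid(array(40, c(2, 2, 2)))
#' m <- structure_mask("PTV", array(TRUE, c(2, 2, 2)))
#' dvh <- compute_cumulative_dvh(g, m)
#' dose_at_volume(dvh, 95)
#' @export
compute_cumulative_dvh <- function(dose, mask, bin_width_gy = 0.05) {
  check_aligned(dose, mask)
  if (!any(mask$values)) stop("empty structure", call. = FALSE)
  if (!is.finite(bin_width_gy) || bin_width_gy <= 0)
    stop("bin_width_gy must be > 0", call. = FALSE)
  doses <- sort(dose$values[mask$values])
  n <- length(doses)
  n_bins <- floor(max(doses) / bin_width_gy - 1e-9) + 2L  # one bin past max
  edges <- seq(0, by = bin_width_gy, length.out = n_bins + 1L)
  # voxels with dose >= edge: n minus the count strictly below the edge
  below <- findInterval(edges, doses, left.open = TRUE)
  frac <- (n - below) / n
  cumulative_dvh(edges, frac, n * voxel_volume_cc(mask), mask$name)
}

#' Dose received by the hottest x% of a structure (Dx%)
#'
#' Returns the dose at which the cumulative curve crosses
#' `volume_percent / 100`, linearly interpolating between the bracketing
#' tabulated points (the ICRU-83 reading: minimum dose received by the
#' hottest x% of the volume). If the curve never drops to the requested
#' fraction the maximum tabulated dose is returned.
#'
#' @param dvh a [cumulative_dvh()].
#' @param volume_percent volume level in percent, strictly between 0 and 100.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, volume_percent) {
  stopifnot(inherits(dvh, "cumulative_dvh"))
  if (!is.finite(volume_percent) || volume_percent <= 0 || volume_percent >= 100)
    stop("volume_percent must lie strictly between 0 and 100", call. = FALSE)
  f <- volume_percent / 100
  vf <- dvh$volume_fraction
  d <- dvh$dose_edges
  at_or_above <- which(vf >= f)
  if (!length(at_or_above)) return(d[1L])
  i <- max(at_or_above)               # rightmost edge still at or above f
  if (i == length(d) || vf[i] == f) return(d[i])
  # interpolate on the segment where the curve crosses f
  d[i] + (d[i + 1L] - d[i]) * (vf[i] - f) / (vf[i] - vf[i + 1L])
}

#' Standard SBRT target dose metrics from a DVH
#'
#' @param dvh a [cumulative_dvh()].
#' @param dmean_gy optional mean dose (computed from the grid via
#'   [mean_dose()]; the DVH alone cannot recover it exactly).
#' @return A list with `dmean`, `d2`, `d95`, `d98` in Gy (`dmean` may be
#'   `NA` when not supplied). `d2 >= d95 >= d98` always holds.
#' @export
dose_metrics <- function(dvh, dmean_gy = NA_real_) {
  list(dmean = dmean_gy,
       d2 = dose_at_volume(dvh, 2),
       d95 = dose_at_volume(dvh, 95),
       d98 = dose_at_volume(dvh, 98))
}

#' Volume-weighted combination of two cumulative DVHs
#'
#' Combines the DVHs of two disjoint structures into the DVH of their union:
#' fractions are averaged with absolute-volume weights on the merged dose
#' axis. Used as the oracle for the partition identity (splitting a target
#' and recombining the sub-DVHs reproduces the whole-target DVH).
#'
#' @param dvh_a,dvh_b [cumulative_dvh()] objects; combined volume `> 0`.
#' @return A [cumulative_dvh()] on the merged dose axis.
#' @export
combine_dvhs <- function(dvh_a, dvh_b) {
  stopifnot(inherits(dvh_a, "cumulative_dvh"), inherits(dvh_b, "cumulative_dvh"))
  va <- dvh_a$total_volume_cc
  vb <- dvh_b$total_volume_cc
  if (va + vb <= 0) stop("zero combined volume", call. = FALSE)
  if (va == 0) return(dvh_b)
  if (vb == 0) return(dvh_a)
  edges <- sort(unique(c(dvh_a$dose_edges, dvh_b$dose_edges)))
  fa <- resample_vf(dvh_a, edges)
  fb <- resample_vf(dvh_b, edges)
  frac <- (va * fa + vb * fb) / (va + vb)
  frac <- rev(cummax(rev(frac)))      # guard monotonicity against fp jitter
  cumulative_dvh(edges, pmin(frac, 1), va + vb,
                 paste(dvh_a$structure, dvh_b$structure, sep = "+"))
}

# Piecewise-linear interpolation of the cumulative curve onto a new axis;
# beyond the last tabulated edge the curve keeps its final value.
resample_vf <- function(dvh, edges) {
  if (length(dvh$dose_edges) == 1L) return(rep(dvh$volume_fraction, length(edges)))
  stats::approx(dvh$dose_edges, dvh$volume_fraction, xout = edges,
                rule = 2, ties = "ordered")$y
}
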