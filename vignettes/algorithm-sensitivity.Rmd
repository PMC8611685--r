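---
title: "Dose-algorithm sensitivity of TCP at the lung–liver boundary: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-algorithm sensitivity of TCP: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbrtTCP)
```

## The problem

When an SBRT target straddles a low-density interface — here a
hepatocellular-carcinoma PTV at the lung–liver boundary — two dose engines
given the *same* plan can disagree by several percent inside the lung part
of the target, because convolution–superposition algorithms model lateral
electron transport only through density scaling of kernels while
transport-solving algorithms handle electronic disequilibrium explicitly.
The clinical question is not which engine is right but how much the
disagreement *matters*: does a 2–5% coverage difference move the predicted
2-year tumour control probability by an amount anyone should care about?

`sbrtTCP` implements that sensitivity analysis end to end. Because the
commercial engines and the underlying patient plans are not available, the
package pairs the analysis chain with a synthetic cohort generator whose
discrepancy structure is an explicit, parameterised model of the phenomenon
(deficit concentrated in lung, near the interface).

## Model and assumptions

**DVH.** A cumulative DVH tabulates `vf(d) = P(dose ≥ d)` over the
structure's voxels at regular bin edges (default bin width 0.05 Gy,
configurable; the axis extends one bin past the structure maximum so the
curve reaches zero). Membership is whole-voxel: a voxel is in or out, with
no partial-volume weighting, because no contouring/voxelisation detail is
available to justify anything finer. Grids and masks must share one
lattice; mismatched lattices are refused rather than resampled, since
silent resampling changes metrics unpredictably at a 2.5 mm grid.

**Dx%.** The "minimum dose received by the hottest x% of the volume":
the dose where the cumulative curve crosses `x/100`, linearly interpolated
between bracketing tabulated points. For piecewise-linear curves this
inverts the curve exactly; for step curves from voxel counting it is exact
to one bin (a uniform 40 Gy structure at 0.05 Gy bins reports D95 =
40.0025 Gy). If the curve never drops to the requested fraction, the
maximum tabulated dose is returned.

**LQ/BED.** `BED = D (1 + (D/n)/(α/β))`, applied edge-wise to the DVH
axis. Every dose level of a plan is treated as delivered in `n` equal
fractions — the only reading consistent with converting a whole DVH of one
plan. No repopulation term and no high-dose LQ modification are applied;
LQ validity at SBRT fraction sizes is a known limitation of the approach
itself, and the package's outputs are intended for *relative* comparison
between arms, not absolute TCP.

**TCP.** The logistic model `TCP = 1/(1 + (D50/D)^(4/γ))` with `D` and
`D50` as BED. `D50` is stored as BED (75.5 Gy, the LQ conversion of
34.9 Gy in 3 fractions at α/β = 10), which makes the model independent of
the fractionation scheme downstream. The exponent is implemented exactly
as `4/γ`, `γ = 1.22`. The published fit leaves the model's "prescription
dose D" under-defined, so the package takes `D` as a configurable DVH
quantile of the whole PTV, defaulting to D95%. The quantile is extracted
on the physical axis and then converted — mathematically equivalent to
extracting it after conversion (the map is monotone), and that commutation
is one of the acceptance properties.

**Paired statistics.** Table-shaped summaries report the mean ± sample SD
of *per-patient* AXB/AAA ratios (not the ratio of cohort means — the only
convention under which per-metric SDs are meaningful), and percent
differences use the reference arm as denominator. The Wilcoxon signed-rank
test discards zero differences, mid-ranks ties, and reports an exact
two-sided p (convolution over the 2^m sign assignments) for m ≤ 20,
switching to a tie-corrected, continuity-corrected normal approximation
above — the `method` field makes the choice auditable. Significance is
two-sided at 0.05 with no multiplicity correction, flagged not corrected.
A fully degenerate cell (identical arms) is reported as p = 1 with a
`degenerate` flag rather than aborting the cohort report.

## Tunable parameters

| Block | Key | Default | Meaning |
|---|---|---|---|
| radiobiology | `d50_bed_gy` | 75.5 Gy | BED at 50% control |
| radiobiology | `gamma` | 1.22 | logistic slope |
| radiobiology | `alpha_beta_gy` | 10 Gy | LQ fractionation sensitivity |
| radiobiology | `n_fractions` | 5 | fractions of the analysed plans |
| radiobiology | `coverage_percent` | 95 | DVH quantile used as the model's D |
| dvh | `bin_width_gy` | 0.05 Gy | DVH bin width |
| synthetic | `n_patients` | 23 | cohort size |
| synthetic | `prescription_pool_gy` | 27.5–50 | 5-fraction prescriptions |
| synthetic | `ptv_volume_range_cc` | 15.4–664 | log-uniform PTV volumes |
| synthetic | `lung_fraction_range` | 0.05–0.6 | uniform PTV lung fractions |
| synthetic | `spacing_mm` | 2.5 mm | lattice spacing |
| synthetic | `dm_*`, `dw_*` | see below | per-arm discrepancy models |
| report | `percent_decimals` | 1 | CSV rounding (JSON keeps full precision) |

## What the generator emulates — and what it does not

Each phantom is two half-spaces (lung above a planar interface, liver
below) with an ellipsoidal PTV whose centre is solved along the interface
normal so the achieved lung-volume fraction lands within 0.05 of its
target. The reference ("AAA-like") field is a plateau of 1.03 ± 0.008 ×
prescription inside the PTV with a sigmoidal falloff reaching 50% at 8 mm
outside the surface; ≥ 95% PTV coverage at prescription and a global
≤ 105% hotspot are enforced, mirroring standard plan-acceptance criteria.

The discrepancy arm multiplies the reference by
`s` in soft tissue and `s·(1 − A·exp(−depth/λ))` in lung, then applies
multiplicative voxel noise (SD 0.005). `s` and `A` are per-patient draws;
`A` is truncated to [0, 0.3] by inverse-CDF sampling, so it is strictly
positive almost surely and the lung part is strictly colder than the soft
part for every patient. The exponential depth profile (λ = 15 mm) is a
stand-in for interface rebuild-up physics; any smooth monotone profile
would satisfy the package's invariants.

Calibration of the shipped defaults (set once, from the arithmetic of
published per-region summaries, and not revisited): for the dose-to-medium
arm, `s = 0.985 ± 0.002` comes directly from a published soft-tissue Dmean
ratio of 98.5 ± 0.2%, and the amplitude mean 0.045 from solving
`0.985·(1 − A) = 0.942` for the lung D98% ratio, with SD 0.045 from the
±4.7 spread; for dose-to-water, `s = 0.998 ± 0.002` and amplitude
0.060 ± 0.045 by the same arithmetic. This is calibration of a stated
world, **not** validation: the generator reproduces the *location and
scale* of the discrepancy, not any patient.

Features of real data deliberately not modelled: curved interfaces and
heterogeneous densities, plan-specific modulation and arc geometry, motion,
organ-at-risk-driven prescription selection (prescriptions are drawn
uniformly from the pool, which is why the synthetic cohort's median TCP
sits well below a real cohort planned mostly at higher doses — percent TCP
differences are correspondingly amplified at low prescriptions), and any
engine physics. A green test therefore establishes that the *pipeline*
(DVH → BED → TCP → paired statistics) is correct and that the generator
obeys its own stated structure; it establishes nothing about AAA or AXB
themselves.

## Numerical choices

- DVH fractions are computed by sorted-search (`findInterval`), asserted
  equal to a brute-force per-voxel counting oracle at every edge in tests.
- Quantile interpolation picks the rightmost tabulated point still at or
  above the requested fraction, then interpolates to the next point; on a
  plateau exactly at the fraction this returns the plateau's right edge.
- Combining sub-DVHs resamples both curves piecewise-linearly onto the
  merged axis and averages with absolute-volume weights; a `cummax` guard
  absorbs floating-point jitter.
- The exact Wilcoxon distribution is built over doubled mid-ranks (always
  integers), making tied ranks exact rather than approximated.
- Truncated-normal draws use the inverse CDF so truncation never produces
  boundary atoms.
- Per-patient streams are derived from `(seed, patient, stage)` by a
  counter scheme (all below 2^31), so cohorts are pure functions of
  `(config, seed)` and extending a cohort leaves existing patients
  bit-identical. Report files are written with fixed formats (`%.17g` for
  exchanged values) so composed CLI stages reproduce the in-memory bundle
  byte for byte.
- An empty sub-volume after the lung/soft split (target entirely in one
  tissue) yields absent metrics and a warning, never zeros.

## Known limitations

- The logistic fit was published for other treatment techniques; absolute
  TCP values carry that transfer error — only paired differences are
  meaningful.
- LQ-based BED at 5.5–10 Gy per fraction is itself contested.
- The planar-interface phantom understates geometric complexity; the
  achieved-lung-fraction tolerance (0.05) can be coarse for the smallest
  targets, where one voxel layer is a large volume fraction.
- DICOM RT ingestion is not provided (no DICOM reader available to R in
  the supported environment); the plain-text grid container and canonical
  DVH CSV are the exchange formats.

## A minimal run

```{r, eval = FALSE}
config <- default_run_config()
config$synthetic$n_patients <- 5
res <- run_pipeline(config, out_dir = tempfile(), seed = 1)
res$summary[res$summary$metric == "D98", ]
res$headline
```
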