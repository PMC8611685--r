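# sbrtTCP

Dose-calculation algorithms disagree most where electronic equilibrium
breaks down — in and near low-density tissue. For stereotactic body
radiation therapy (SBRT) of hepatocellular carcinoma at the lung–liver
boundary, part of the planning target volume (PTV) sits in lung, and a
transport-accurate algorithm (Acuros XB–like, reported as dose-to-medium
Dm or dose-to-water Dw) typically reports lower target coverage there than
a convolution–superposition algorithm (AAA-like). `sbrtTCP` quantifies how
such paired dose differences propagate into PTV dose metrics and 2-year
tumour control probability (TCP).

The package is aimed at medical-physics researchers who want the full
analysis chain as reusable, tested code — without the commercial dose
engines and without patient data: a seeded synthetic phantom-cohort
generator stands in for both.

## The model chain

1. **DVH extraction.** From a 3-D dose grid and aligned binary masks, the
   cumulative dose–volume histogram of the whole PTV and of its lung /
   soft-tissue parts (`PTV = PTV_Lung ∪ PTV_SoftTissue`, split by a lung
   mask), with the metrics Dmean, D2%, D95%, D98% (Dx% = minimum dose to
   the hottest x% of the volume, interpolated).
2. **LQ/BED conversion.** `BED = D (1 + (D/n)/(α/β))` with `α/β = 10 Gy`
   and `n` the number of fractions.
3. **Logistic TCP.**

   `TCP = 1 / (1 + (D50/D)^(4/γ))`

   with `D50 = 75.5 Gy` BED (the BED of 34.9 Gy in 3 fractions), slope
   `γ = 1.22`, and `D` the BED of the whole-PTV D95% (configurable
   quantile). TCP is exactly 0.5 at `D = D50`.
4. **Paired cohort statistics.** Per-patient AXB/AAA ratios summarised as
   mean ± SD per region and metric, two-sided Wilcoxon signed-rank tests
   (exact by enumeration for ≤ 20 informative pairs, tie-corrected normal
   approximation above), and per-patient %ΔD95 vs %ΔTCP.
5. **Synthetic cohort.** Ellipsoidal PTVs (15.4–664 cc, log-uniform)
   straddling a planar lung–liver interface on a 2.5 mm lattice;
   prescriptions drawn from {27.5, 30, 35, 40, 45, 50} Gy in 5 fractions; a
   smooth reference plan covering ≥ 95% of the PTV with a ≤ 105% hotspot
   cap; and per-arm multiplicative discrepancy fields whose dose deficit is
   concentrated in lung near the interface.

## Worked example

```r
library(sbrtTCP)
config <- default_run_config()         # all published constants live here
res <- run_pipeline(config, out_dir = "results/demo", seed = 42)
str(res$headline)
```

```
List of 3
 $ mean_pct_diff_tcp : Named num [1:2] 14.9 12.6
  ..- attr(*, "names")= chr [1:2] "Dm/AAA" "Dw/AAA"
 $ max_pct_diff_tcp  : Named num [1:2] 35.7 37.4
  ..- attr(*, "names")= chr [1:2] "Dm/AAA" "Dw/AAA"
 $ median_tcp_percent: Named num [1:3] 32.8 28.5 29
  ..- attr(*, "names")= chr [1:3] "AAA" "AXB_Dm" "AXB_Dw"
```

The headline block says: over this 23-phantom synthetic cohort, the
Dm-like recalculation lowers 2-year TCP by 14.9% on average (relative to
the AAA-like arm, worst case 35.7%), and the cohort's median TCP drops
from 32.8% (AAA) to 28.5% (Dm). The summary table mirrors the clinical
report shape — e.g. for this seed

```
region,metric,comparison,mean_ratio_percent,sd_ratio_percent,p_value,method,n
PTV_SoftTissue,Dmean,Dm/AAA,98.4,0.2,2.889e-05,normal,23
PTV_Lung,Dmean,Dm/AAA,95.3,2.6,2.889e-05,normal,23
```

soft-tissue mean dose is 98.4 ± 0.2% of the reference while the lung part
is 95.3 ± 2.6%: the discrepancy concentrates in lung, and the spread
across phantoms is an order of magnitude larger there. The per-patient
file `figure_tcp_vs_d95.csv` pairs each phantom's %ΔD95 with its %ΔTCP
(e.g. `P01,Dm/AAA,7.0,10.4`: a 7.0% D95 deficit costs 10.4% of TCP).

These are *synthetic* numbers: the generator is calibrated to published
per-region ratio summaries, not fitted to patient data, and percent TCP
differences are amplified for low-prescription phantoms.

The same bundle can be produced stage by stage on the command line
(`exec/sbrt-tcp`, or `Rscript -e 'sbrtTCP::sbrt_tcp_cli()' ...`):

```sh
sbrt-tcp simulate --config run.ini --out cohort/
sbrt-tcp metrics  --in cohort/ --config run.ini --out metrics.csv
sbrt-tcp compare  --in metrics.csv --config run.ini --out report/
sbrt-tcp report   --in metrics.csv --config run.ini --out report/headline.json --seed 1
```

Composed stages are byte-identical to `run_pipeline()` for the same config
and seed.

## Documentation

The methods vignette (`vignettes/algorithm-sensitivity.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, and the
package's numerical conventions.
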