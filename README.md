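# neobat

Quantification of brown adipose tissue (BAT) depot volume and fat fraction
from two-point Dixon water–fat separated MRI of human neonates, with a
ground-truthed synthetic phantom generator that makes every stage of the
pipeline testable without scan data.

## The science

BAT is multilocular and water-rich; white adipose tissue (WAT) is
unilocular and fat-rich. On chemical-shift water–fat MRI they separate on
the **fat signal fraction**

    FF = F / (F + W),

the ratio of fat signal to the combined signal from fat and water, computed
per voxel from in-phase (`IP = W + F`) and opposed-phase (`OP = |W − F|`)
magnitude echoes. Ex vivo rodent adipose puts excised BAT at 43.7 ± 7.8 %
FF and perirenal WAT at 73.3 ± 10.4 %; an ROC analysis of those samples
yields the 20–60 % FF band used to classify BAT. In sleeping neonates the
band isolates bilateral supraclavicular, axillary and spinal (T1–T5) BAT
depots, quantified against subcutaneous nuchal WAT (≈ 68 % FF).

The package implements, as ordinary R functions:

* `separate_water_fat()`, `compute_fat_fraction()`, `signal_mask()`,
  `flag_swaps()` — magnitude dual-echo separation, FF mapping with
  validity masking, appreciable-signal masking, and advisory fat/water
  swap detection;
* `bat_candidate_mask()` — the three-criterion rule-based BAT
  visualization mask;
* `segment_bat_region()`, `segment_wat_nuchal()`, `union_region()` —
  threshold-constrained seeded region growing (one voxel shell per
  iteration with curvature smoothing; iterations are the stopping rule);
* `depot_stats()`, `cohort_summary()`, `paired_wat_bat()`,
  `ff_volume_correlation()` — depot volume (cc) and FF statistics and the
  cohort-level comparisons;
* `icc_decompose()`, `reliability_report()`, `rescan_agreement()`,
  `roc_calibrate()` — two-way random-effects ICC/WSC/N variance
  decomposition, scan–rescan voxelwise agreement, ROC threshold
  calibration;
* `make_vial_phantom()`, `make_torso_phantom()`, `make_cohort()`,
  `make_rescan()`, `jitter_seeds()` — the synthetic data generator
  (skew-normal tissue FF distributions moment-matched to printed
  statistics, ellipsoidal depots with analytic volumes, dual-echo forward
  model, scan–rescan replicates, rater seed jitter);
* `run_pipeline()` / `run_cohort_pipeline()` — end-to-end orchestration
  with manifests and swap-based subject exclusion.

## Worked example

Twenty-two synthetic neonates drawn from the printed cohort statistics,
segmented and quantified end to end (≈ 25 s):

```r
library(neobat)
run <- run_cohort_pipeline(cohort_spec(n_subjects = 22, seed = 42))
run$summary[, c("region", "volume_mean_cc", "volume_sd_cc", "ff_mean_pct")]
#>            region volume_mean_cc volume_sd_cc ff_mean_pct
#> 1 supraclavicular           2.78         1.39        29.4
#> 2        axillary           3.55         1.77        29.4
#> 3           union           6.33         3.16        29.4
#> 4           spine           3.82         1.78        32.3
#> 5      nuchal_wat           4.95         1.46        67.9
run$paired$delta_pct
#> [1] 38.49  # mean paired WAT − BAT fat-fraction difference, in points
```

The union (supraclavicular + axillary) depot comes back at 6.3 cc and
29.4 % FF against generative truths of 6.50 cc and 29.5 %; nuchal WAT at
67.9 % FF against 67.7 %; and WAT exceeds BAT by ≈ 38 percentage points in
every subject. The ex vivo side of the story:

```r
bat <- sample_ff(tissue_distribution("bat", 0.437, 0.078, -0.27), 1e6)
wat <- sample_ff(tissue_distribution("wat", 0.733, 0.104, -0.85), 1e6)
roc <- roc_calibrate(bat, wat)
100 * c(roc$operating$bat_below_060, roc$operating$bat_above_020)
#> [1] 98.8 99.7  # BAT correctly classified at the 60% and 20% cuts
```

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study arc and write
their tables under `results/`:

1. `01_exvivo_roc.R` — ex vivo vial phantoms, FF contrast (BAT 43.8 % vs
   WAT 73.0 % measured; 29.2-point contrast) and ROC calibration of the
   20/60 % band;
2. `02_cohort_quantify.R` — the 22-subject cohort summary table, paired
   WAT − BAT comparison and FF–volume correlations;
3. `03_rescan.R` — scan–rescan voxelwise agreement per compartment
   (≈ 2.5-point mean FF residual; tissue contrast ≈ 18-fold larger);
4. `04_reliability.R` — jitter-based multi-rater study plus
   variance-component simulations showing the ICC/WSC/N estimator recovers
   the 0.41–0.97 reliability regime at n = 22.

Run them from the repository root with `Rscript analysis/01_exvivo_roc.R`
and so on, after installing the package.

## Layout

```
R/                  implementation (phantom, dixon, batmask, segment,
                    quantify, reliability, roc, io, pipeline)
analysis/           numbered workflow drivers (write to results/)
results/            tables produced by the analysis drivers
scripts/acceptance.R  headline-quantity reproduction script
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, parameters, design choices)
```
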