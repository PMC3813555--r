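---
title: "Quantifying neonatal brown adipose tissue from water-fat MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neonatal brown adipose tissue from water-fat MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Brown adipose tissue (BAT) is multilocular, mitochondria-rich and
water-rich; white adipose tissue (WAT) is unilocular and fat-rich. On
chemical-shift water-fat MRI the two therefore separate on the **fat signal
fraction**

$$\mathrm{FF} = \frac{F}{F + W},$$

the ratio of fat signal to the combined signal from fat and water. Ex vivo
rodent measurements put excised interscapular BAT at 43.7 ± 7.8 % FF and
perirenal WAT at 73.3 ± 10.4 %, and an ROC analysis of those samples
motivates classifying BAT inside a 20–60 % FF band. In neonates imaged
during natural sleep, the same band isolates bilateral supraclavicular,
axillary and spinal (T1–T5) BAT depots, with subcutaneous nuchal WAT as the
fat-rich reference region (67.7 ± 4.6 % FF).

`neobat` implements the full quantification chain — magnitude two-point
Dixon separation, FF mapping, rule-based BAT candidate masking,
threshold-constrained seeded segmentation, depot volume/FF statistics with
cohort aggregation, scan–rescan agreement and ICC/WSC/N reliability
decomposition — driven by a synthetic phantom generator, so that every
stage is verifiable against known ground truth without any scan data
(none were deposited with the original study).

## The forward model and its inversion

The dual-echo magnitude model is

$$\mathrm{IP} = W + F + \varepsilon_1, \qquad
  \mathrm{OP} = |W - F| + \varepsilon_2,$$

with independent additive Gaussian noise on each echo (a deliberate
simplification of Rician magnitude statistics, negligible at the simulated
SNR) and magnitudes clipped at zero. The algebraic inversion
$(\mathrm{IP}+\mathrm{OP})/2$, $(\mathrm{IP}-\mathrm{OP})/2$ recovers the
*larger* and *smaller* compartment; deciding which is water requires a
dominance decision, because the opposed-phase magnitude discards the sign
of $W - F$. This is precisely the fat/water **swap ambiguity** that vendor
reconstructions resolve with phase information. Since phase modelling is
out of scope here, the phantom emits the vendor-style per-voxel dominance
field alongside the echoes, emulating the scanner reconstruction the
original analysis started from; `separate_water_fat()` accepts `"water"`,
`"fat"`, or that field. Swap artifacts are simulated by corrupting the
dominance field inside declared regions, and `flag_swaps()` detects the
resulting near-complementary FF components (advisory only; the pipeline
excludes subjects with swaps inside BAT analysis regions, mirroring the
study's exclusion policy).

Negative post-clip mass is tracked two ways: image-wide, and restricted to
appreciable-signal voxels. Only the latter drives the "noise too high for
magnitude Dixon" warning (threshold 1 % of in-tissue signal), because in
any air-dominated magnitude image roughly half the background voxels clip
by a small amount purely by construction.

FF is defined where $F + W > 10^{-6} \times \max(F+W)$, which avoids 0/0 in
background air; everything else is carried as an explicit validity mask.
FF is stored as a fraction in $[0,1]$; reports render percent.

## Tissue fat-fraction distributions

Tissue FF histograms are summarized in the source material by mean, SD and
skewness only, so tissues are modelled with the three-parameter
**skew-normal** family — the simplest unimodal law pinned down exactly by
those three moments. Moment inversion is closed-form; the representable
skewness range is $|\gamma_1| < 0.99527$ and anything outside is rejected
as unrepresentable. Draws are clipped to $[0,1]$ with the clip fraction
reported (negligible for all tissues used here).

```{r}
library(neobat)
x <- sample_ff(tissue_distribution("bat", 0.437, 0.078, -0.27), 1e6)
c(mean(x), sd(x))        # 0.437, 0.078
mean(x < 0.60); mean(x > 0.20) # ~0.988, ~0.997
```

A consequence worth knowing: the skew-normal matched to the WAT moments
(73.3 %, 10.4 %, −0.85) places ≈ 11.4 % of its mass below 60 % FF, slightly
above the "< 10 %" operating point reported for the empirical ex vivo
samples. The empirical WAT distribution was described as gamma-like because
of the FF ceiling; a moment-matched skew-normal slightly overweights that
lower tail. The package reports the computed value rather than adjusting
the model to the printed operating point.

## The phantom

Depots are axis-aligned ellipsoids (cylinders for the ex vivo vials), so
every true volume has a closed form and rasterized voxel counts can be
checked against analytic volumes. The neonate torso uses a 128 × 96 × 64
grid at the acquisition voxel size of 0.97 × 0.97 × 1 mm — the full
acquisition matrix (512 × 320 × 160) adds nothing at desk scale, while
keeping the printed voxel size makes all volume arithmetic match. The
torso body is water-rich soft tissue (FF 0.08) at a lower total signal
(0.30 vs 1.0 for adipose), reflecting the relative darkness of muscle on
this kind of gradient-echo acquisition; this also means the
appreciable-signal mask (total > image mean + 2 SD, background included)
isolates adipose tissue, which is what makes the lowest-quartile fat-image
threshold for WAT segmentation spatially selective. The default echo noise
SD (0.04 of adipose signal) and within-depot voxelwise FF SD (0.03) were
chosen once as realistic in vivo values; together they reproduce
scan–rescan FF residuals of ≈ 2.5 percentage points, the regime reported
for repeated acquisitions.

Cohorts draw subject-level truths from the printed between-subject
distributions: union (supraclavicular + axillary) volume 6.50 ± 3.10 cc
split 2.95 : 3.76 between its components, union FF 29.5 ± 3.7 %, spinal
volume 3.65 ± 1.40 cc and FF 32.2 ± 3.2 %, nuchal WAT FF 67.7 ± 4.6 %.
Nuchal WAT volume is not printed anywhere and defaults to 5.0 ± 1.5 cc, a
mid-range subcutaneous depot. Volume and FF are coupled by a Gaussian
copula at the printed correlations (union 0.56, spine 0.84). By default
the subject-level draws are **stratified** (Latin-hypercube style): one
draw per equiprobable stratum in random order. Marginals are unchanged,
but a 22-subject cohort is then representative of the distribution it was
asked to carry instead of a single noisy realization whose mean wanders by
±0.66 cc; plain iid sampling is available with `stratified = FALSE`. The
layout keeps all depots pairwise disjoint for draws beyond +5 SD of every
distribution; more extreme draws fail loudly with a geometry error rather
than silently merging depots.

## Segmentation

The interactive protocol being reproduced seeds 3 mm bubbles in depots
(≤ 4 per side for supraclavicular and axillary, one per side per vertebra,
T1–T5 only), constrains the evolution to the 20–60 % FF band, and treats
the iteration count as the stopping rule (50 for supraclavicular/axillary,
40–60 with default 50 for spine). Nuchal WAT uses a single 5 mm seed on
the fat image thresholded above its lowest quartile (computed within the
appreciable-signal mask) and 100 iterations.

The continuous active-contour evolution is modelled as **morphological
region growing at one voxel shell per iteration**: a voxel is annexed only
if it is eligible and at least `min_neighbors` (default 3) of its 26
neighbours are already in the region, which acts as the curvature
smoothing term — single-voxel spikes do not propagate. This maps
iterations one-to-one onto growth shells, making the protocol's iteration
budget meaningful, and gives three properties the tests rely on:
confinement (the region never leaves the eligibility set), monotone growth
in the iteration count, and a fixed point (iterating past convergence is a
no-op, so the implementation may stop early without changing the result).
Seed bubbles are rasterized as spheres in physical mm (anisotropic voxels
respected) and intersected with the eligibility set, keeping confinement
unconditional; zero iterations return exactly those rasterized bubbles.
Canonical phantom seeds sit at depot centroids ("rater 0"); because a
centroid voxel can be pushed out of the band by noise, the pipeline snaps
seeds to the nearest eligible voxel within 4 mm first — the automated
analogue of a rater placing seeds on visibly in-band voxels.

One consequence of convergent growth deserves emphasis: on these phantoms
the segmentation is essentially **seed-independent** — any in-depot seed
reaches the same connected eligibility component. A jitter-based
multi-rater study therefore yields ICC ≈ 1 with zero rater variance. That
is a faithful statement about the phantom, not about neonates: in vivo
rater variance is driven by partial-volume gradients and ambiguous
anatomical borders that the crisp phantom deliberately lacks. The
reliability estimator is therefore validated on variance-component
simulations spanning the reported ICC regime (0.41–0.97), and the
"union is more rater-robust than its parts" property is demonstrated on a
phantom with two depots joined by an in-band corridor under a
non-converged iteration budget — the only regime in which seed placement
can move the result at all.

## Rule-based BAT candidate mask

The three-criterion visualization mask includes a voxel when (1) total
signal exceeds the entire-image mean by 2 SD, (2) the fat signal clears a
1 SD offset below the entire-image fat mean, and (3) FF > 20 % with no
upper bound. The stated direction of criterion 2 is grammatically
ambiguous ("fat signal greater than one SD below the mean"). The
upper-bound reading (fat < mean − SD) turns out to be self-defeating: for
criterion 1 to select anything the image must be background-dominated
(tissue fraction ≲ 20 %), and on any background-dominated fat image
mean − SD is negative, so an upper bound excludes every voxel. The package
defaults to the lower-bound reading (fat > mean − SD), which excludes
water-only and noise voxels and degrades to vacuous when mean − SD < 0;
the alternative reading remains available via `fat_direction = "below"`.
Note that under either reading WAT satisfies all three criteria — the
mask is a visualization and seeding-QC aid; separating BAT from WAT is the
job of the segmentation band's 60 % upper bound.

## Quantification and reliability

Depot volume is voxel count × voxel volume (0.9409 mm³ → cc); FF
statistics use all valid FF voxels in the final mask without
re-thresholding. Cohort summaries report mean, sample SD (n − 1) and range;
FF in percent to one decimal. The paired WAT − BAT comparison reports both
the mean of paired differences and the difference of means (identical on a
complete layout) with a two-sided paired Student t test (Wilcoxon
available); zero-variance differences are reported as degenerate rather
than producing a spurious p-value.

ICC/WSC/N use a two-way random-effects, single-measurement decomposition:
subject, rater and residual variance components estimated from the ANOVA
expected mean squares, negative estimates truncated at zero (standard
practice) and the three ratios renormalized, so ICC + WSC + N = 1 holds by
construction and all three are invariant to affine rescaling of the
measurements. With three ratings (1a, 1b by one rater, 2 by another),
inter-rater values average the (1a, 2) and (1b, 2) decompositions and
intra-rater uses (1a, 1b). Scan–rescan agreement computes voxelwise
Pearson correlation (matching the linear scatter being emulated) and mean
absolute FF residual per compartment, with no registration between
acquisitions; compartments under 10 valid voxels are skipped with a
warning.

ROC calibration sweeps thresholds at 0.001 FF granularity; the upper
threshold is the largest cut with WAT false-positive rate < 10 %, the
lower the largest cut keeping BAT classification ≥ 99.9 %, and the AUC is
computed by the trapezoid rule (equal, on grid-aligned samples, to the
brute-force pairwise comparison probability — a test oracle).

## Problem sizes

The test suite and acceptance script run everything at the sizes the
analyses use: $10^6$ Monte-Carlo draws for threshold operating points, the
full 128 × 96 × 64 grid for torso phantoms, 22-subject cohorts for the
in vivo analogue (≈ 25 s end to end), and 40-replicate simulations for the
reliability and rescan oracles. Small custom grids (48 × 40 × 32) are used
for segmentation property loops where the full torso adds nothing.

## Known limitations

* Magnitude-only two-point Dixon: no multi-peak fat spectrum, no T1/T2*
  correction, no noise-bias correction of the FF ratio, no complex-phase
  swap *correction* (swaps are simulated and flagged, never repaired).
* The phantom's crisp ellipsoidal depots lack partial-volume gradients,
  anatomical ambiguity and motion, so rater-variance magnitudes and
  scan–rescan correlations on phantoms do not transfer to in vivo values;
  the machinery that measures them does.
* Depot FF within a subject is drawn symmetrically; the ex vivo negative
  skewness is available for vials but not applied to in vivo depots, whose
  printed statistics are means and SDs only.
* No registration between scan and rescan; the rescan differs only by
  noise and an optional smooth bias field, not by repositioning.
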