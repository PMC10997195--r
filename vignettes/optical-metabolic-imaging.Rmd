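---
title: "Quantifying metabolic heterogeneity from longitudinal optical imaging"
author: "omiHet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metabolic heterogeneity from longitudinal optical imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omiHet)
```

## The measurement problem

Intravital window-chamber imaging of tumor xenografts produces repeated
single-channel fluorescence frames per animal and session: a 60-min probe
frame for each metabolic endpoint — TMRE (mitochondrial membrane
potential), 2-NBDG (glucose uptake), Bodipy FL C16 (fatty-acid uptake) —
plus a laser-off dark-noise frame and a pre-injection background frame,
and a Rhodamine B solid standard imaged once per session. The analysis
questions are distributional (how does the pixel-intensity distribution of
a probe shift across treatment stages?) and spatial (what fraction of the
tumor area is glycolytic vs oxidative?), asked per animal and longitudinally
across a treatment/regression/recurrence time course. omiHet implements
this pipeline end-to-end, together with a synthetic-cohort generator with
recorded ground truth so that every stage can be validated without access
to animal data.

## Frame correction and calibration

Each probe frame is corrected by scalar (whole-frame mean) subtraction of
the dark-noise frame and of the pre-injection background. Because the
pre-injection frame itself contains dark current, its dark-subtracted mean
is used, so dark current is removed exactly once:

```
corrected = raw - mean(dark) - (mean(preinjection) - mean(dark))
```

Negative pixels are clamped to zero: fluorescence is non-negative and the
downstream cluster cutoffs assume it. Daily light-source variation is then
removed by ratio calibration against the session's Rhodamine B reading,
`values = corrected * reference/session`, with the first session's reading
as the default reference. A subtractive calibration would not commute with
source-intensity scaling, whereas the divisive form makes the corrected
image invariant under a common gain applied to all frames and the standard
— a property the test suite checks. The whole frame is the analysis
region; pixels outside the tumor fall into the low/low cluster, which the
area-fraction stage excludes by design.

## Trajectories and disease stages

Tumor volume is computed from caliper diameters as
`short^2 x long / 2` (mm^3), with swapped entries auto-corrected under a
warning. Stages partition the day axis: measurements at or before
treatment start are `primary`; during active treatment,
`early_regression`; after withdrawal while volume still declines,
`late_regression`; `residual` once the relative change between consecutive
measurements falls below a plateau tolerance (default 5%, configurable —
no numeric criterion exists for "no active growth", so this is a package
decision); and `recurrence` once volume climbs back above the minimum by
more than the same tolerance. Untreated animals are `untreated_growth`
throughout.

## Blocked-permutation KS tests

Pixel distributions are pooled across all pixels and all mice of a group
("mice contribute proportionally to their pixel counts"), and two pools
are compared with the Kolmogorov–Smirnov statistic
`D = sup |ECDF_a - ECDF_b|` computed on unbinned values. Pixels within one
animal are strongly dependent, so the permutation null never moves single
pixels: the exchangeable unit is the mouse block. Two schemes cover the
two comparison types that arise:

* **exchange** (default, unpaired): mouse blocks are reassigned between
  the groups, preserving group sizes — for comparisons such as
  day-matched resistant vs sensitive animals;
* **flip** (paired): each mouse appearing in both groups has its two
  value sets swapped with probability 1/2 — for longitudinal
  comparisons of the same animals across time points.

With `nPerm = 1000` (the default) and few animals, the number of distinct
block assignments is often below the requested permutation count; the
implementation then enumerates the null exhaustively and reports the exact
p-value (`nPerm` records the enumeration count). Monte-Carlo mode uses the
add-one convention `p = (1 + #(D* >= D)) / (nPerm + 1)`, which keeps p in
(0, 1]. Internally, D for thousands of assignments reduces to one matrix
product over per-block cumulative pixel counts at the pooled order
statistics, which is what makes the 2000-replicate type-I sweep in the
acceptance suite cheap. Ridge-plot binning (`binForRidge`) happens strictly
after statistics and never affects them.

## 2x2 metabolic clustering and area fractions

Cluster analysis thresholds co-registered 2-NBDG and TMRE frames pixel by
pixel at per-probe cutoffs — the mean (or median) of the pooled pixel
values — into four classes: LL, HL, LH, HH, writing the 2-NBDG level
first (HL is glycolytic, LH oxidative). Ties go Low; with continuous data
this is a measure-zero decision, and it keeps assignment deterministic.
Two pooling scopes are provided because the source procedure is ambiguous
between them: the default pools all pixels of a cohort across all time
points (a fixed ruler, required for longitudinal comparability), while a
per-time-point scope is selectable; the scope used is recorded in the
`CutoffPair`. Area fractions are percentages of the *non-LL* pixel count —
LL pixels are background and vasculature — and LL exclusion is applied per
image, before any averaging. Stage-level percentages are unweighted means
of the per-time-point percentages, pooled or per mouse. Group differences
use one-way ANOVA with Tukey HSD; a zero-variance input returns F = 0,
p = 1 rather than erroring, which legitimately occurs on noiseless
synthetic fixtures.

## Metabolomics stage

The metabolite table (samples x metabolites, no filtering or imputation)
passes through an enforced, recorded stage order: sum normalization (each
sample divided by its total), natural-log transform, Pareto scaling
(center, divide by the square root of the standard deviation). Each stage
adds a named assay to the `MetaboliteSet`, so intermediate scales stay
available. Two decisions deserve note. First, the log base: the transform
is natural-log, but fold changes are always reported in log2, matching how
volcano results are read. Second, the fold-change stage: Pareto scaling
destroys fold-change units, so `volcanoTable` takes its log2 fold change
from the sum-normalized values while the two-sided pooled-variance t-test
runs on the fully processed values (per metabolite the Pareto map is
affine, so this t equals the t on log values). Significance is the dual
threshold p < 0.05 and |log2FC| > 0.05. Batch centering subtracts the
per-batch median per metabolite on the log scale — medians rather than
means, for robustness to outlying samples — before cross-batch
single-metabolite ANOVA.

## The synthetic-cohort generator

The generator defines the conditions under which the pipeline is
validated:

* **Trajectories** are piecewise exponential with the response waypoints
  of the emulated study: treated-resistant tumors at 70% of baseline by
  D4 and 40% by D18, a slow decline to a residual plateau (22% of
  baseline) at D40, flat to D60, then regrowth reaching baseline near
  D90; treated-sensitive tumors decay without regrowth to sub-palpable
  volume by D120; untreated tumors grow exponentially (rate 0.066/day,
  ten-fold in ~35 days). Caliper noise is lognormal with sd 0.08,
  a realistic hand-measurement error.
* **Images** place four metabolic subpopulations as contiguous blobs.
  Rather than a seed-site tessellation — whose cell-area variance cannot
  guarantee requested area weights — subpopulations are the quantile
  level sets of a Gaussian random field smoothed to the blob scale
  (default 12 px): organic contiguous regions with *exact* pixel quotas.
  Class mean levels are 60 AU (low) and 300 AU (high) per probe with
  planted cutoffs at 180 AU; additive Gaussian read noise (default sd 12,
  5% of the 240 AU class contrast), a constant 40 AU dark current, a
  smooth ±12 AU background gradient, per-session light-source drift in
  [0.8, 1.25] mirrored by the standard reading, and a lognormal per-mouse
  factor (sd 0.05) complete the forward model. The margins are wide
  enough that with noise off the full pipeline reproduces the truth mask
  with zero mislabeled pixels.
* **Metabolite tables** are lognormal around group means separated by
  planted log2 fold changes (multiplicative batch offsets on top), five
  samples per group by default.

All randomness flows from one root seed through a string-hash stream
derivation (`deriveSeed`), so any single artifact is regenerable in
isolation and full runs replay byte-identically. What the generator does
*not* emulate: optical physics (PSF, depth attenuation), vascular
structure, probe pharmacokinetics, and real pixel-intensity distribution
shapes, which are broad and overlapping rather than well-separated modes.
Passing recovery tests therefore demonstrates correctness of the
computational procedure, not detector-level robustness on real images.

## Numerical and validation choices

Validation sizes are chosen to exercise each property at meaningful
resolution while staying quick: 200 random instances against a
brute-force ECDF oracle for the KS statistic (agreement to 1e-12); a
2000-replicate block-wise null sweep (5 blocks per group, 500 pixels per
block) for the type-I error of the blocked test; 128x128 cohorts for
cluster recovery (planted 40/30/20/10 weights recovered within 2
percentage points at noise equal to 10% of class contrast); 500
simulations at n = 5 per group for volcano power (unit planted effects
detected in well over 80% of runs, null metabolites flagged at the
nominal ~5%). The cutoff-robustness check uses marginally balanced
("symmetric") mixes — per-probe pools split 50/50 high/low — because that
is the regime in which a median cutoff is guaranteed to fall in the same
inter-mode gap as the mean cutoff; per-cluster group orderings are then
identical under either method. TIFF frames are encoded as 32-bit samples
against a fixed 4096 AU full scale (round-trip error below 1e-6 AU),
since the TIFF writer stores samples on [0, 1].

## Worked example

```{r example, eval = FALSE}
cfg <- demoConfig("omihet-demo", seed = 1)
report <- runPipeline(cfg)
report$stage_fractions
read.csv(file.path("omihet-demo", "ks_results.csv"))
```

## Known limitations

No image registration across days and no ROI segmentation (the whole
frame is analyzed, with LL absorbing background); no flat-field
correction; no multiple-testing correction across pairwise KS tests (per
test p only); Bodipy participates in distribution comparisons but not in
the 2x2 cluster space; the ANOVA assumes approximate normality of
per-mouse fractions, which the small group sizes cannot verify.
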