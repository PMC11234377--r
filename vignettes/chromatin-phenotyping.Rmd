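---
title: "Quantifying chromatin heterogeneity from high-throughput nucleus imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin heterogeneity from high-throughput nucleus imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Cultured plant protoplasts reorganise their chromatin within days of
isolation. Two fluorescent chromatin reporters are imaged together: a core
nucleosome marker (H2B--RFP, read here as "total chromatin") and a linker
histone marker (H1.2--GFP). Three questions drive the analysis:

1. How does the relative abundance of linker histone (the per-nucleus
   GFP:RFP mean-intensity ratio) change over culturing days?
2. How do nuclear morphology and the spatial texture of chromatin change,
   summarised by principal components of a large feature set?
3. How heterogeneous is the population cell-to-cell, measured as the
   discretised Shannon entropy $H_0$ of each feature's distribution across
   nuclei, and how does that heterogeneity evolve ($\Delta H_0$ between
   days) under different culture conditions?

`chromaphen` implements the full chain: image simulation with ground truth,
projection and illumination correction, segmentation, a 370-feature
registry, SVM-based segmentation quality control, and the ratio, PCA and
entropy analyses.

# Pipeline stages and their assumptions

## Projection and illumination correction

Z-stacks are reduced by maximum-intensity projection per channel
(`max_project()`). Correction (`correct_illumination()`) is retrospective
flat-fielding: the per-pixel mean across all fields of an experiment,
smoothed with a wide Gaussian (default $\sigma = 50$ px), normalised to
mean 1 and divided out. This assumes the illumination bias is shared across
fields and smooth at scales well above a nucleus diameter. The bias is
floored at $10^{-3}$ to keep divisions finite; correction is applied after
projection, which is adequate because only projections are analysed
downstream. Correction preserves each channel's global mean to within 1%
and is idempotent to within 0.1%.

## Segmentation

`segment_nuclei()` follows a deliberately simple recipe on the
total-chromatin channel: Gaussian smoothing with a 5-pixel kernel
($\sigma$ = size/4, truncated to size$\times$size), Otsu thresholding
restricted to a user-defined intensity range, binarisation, hole filling,
removal of components below 200 px (strict), and 8-connected labelling with
border flags. The *ranged* Otsu matters: with bright chromocenters inside
nuclei, an unrestricted between-class-variance optimum can sit inside the
nucleus intensity distribution, splitting bright subregions from dim nuclei
instead of nuclei from background. The admissible range should bracket the
background--nucleus gap; for the simulator's intensity units the pipeline
default is `c(0.03, 0.10)` (background $\approx$ 0.02, nucleus base
$\approx$ 0.25). Ties in the criterion break toward the lower threshold.
Touching nuclei are *not* split by watershed; under-segmentations are
instead rejected by the QC classifier, which keeps the geometry of every
retained object trustworthy.

## The feature registry

Features are measured on the *unsmoothed*, illumination-corrected rasters;
the segmentation-time smoothing never enters a measurement. The registry
fixes 370 columns: 16 morphology features shared between channels (derived
from the mask alone) and 177 per channel — 12 intensity statistics, 7 Hu
moment invariants, 4 Gabor filter-bank responses, 54 threshold adjacency
statistics (TAS) and 100 local binary pattern (LBP) values. Each channel
thus carries 193 metrics (177 + 16 shared). The split across families is a
design decision of this package: the totals and the named methods pin the
registry down, and LBP radii 1–10 with the 10-bin rotation-invariant
uniform histogram reproduce both printed totals exactly
($16 + 2\times(12+7+4+54+100) = 370$).

Numerical choices worth knowing:

* **Perimeter** uses a Kulpa-corrected chain length (0.948 per straight
  step, 1.340 per diagonal step of the boundary trace), so digitised disks
  measure $\approx 2\pi r$ and circularity of a disk is $\approx 1$.
* **LBP** samples 8 neighbours per radius by bilinear interpolation; a bit
  is set when the neighbour is $\geq$ the centre within a relative
  tolerance of $10^{-9}$, so interpolation round-off on exact ties (flat
  regions) cannot flip bits. Codes with more than two circular transitions
  map to the non-uniform label 9. Pixels whose sampling circle leaves the
  image are excluded rather than padded — no fabricated intensities.
* **TAS** thresholds with three windows around the object mean
  ($\mu$, $\mu \pm \sigma$) and histograms white-neighbour counts for the
  binary image and its in-mask complement; empty white sets give defined
  all-zero histograms.
* **Gabor** uses quadrature pairs at wavelengths {2, 4, 8, 16} px and four
  orientations, DC-free even kernels, magnitude responses maximised over
  orientation, averaged over the object. Responses are homogeneous of
  degree 1 in the signal and orientation-symmetric by construction.
* **Hu** invariants are intensity-weighted and reported as
  $-\mathrm{sign}(h)\log_{10}(|h| + 10^{-30})$.

## Segmentation quality control

The interactive annotation step of high-content workflows is replaced by
programmatic labels: a segmented object is "correctly segmented" (class A)
iff it is the one-to-one best match of a true *good* nucleus at
IoU $\geq$ 0.7. An RBF-kernel SVM (C = 1) is trained on seven features —
area, circularity, roundness, elongation, convexity and the two channel
mean intensities — z-scored with training statistics. Objects predicted
mis-segmented are dropped, then giant outliers with area strictly above
5000 px. On the benchmark fixture (10 fields, ~1000 labelled objects, ~20%
distractors) 5-fold cross-validated accuracy exceeds 0.95.

## PCA with SVD imputation

Nuclei are collapsed to per-well medians (wells are the replication unit
for the scatter; individual nuclei are later *projected* onto the same
loadings for density maps — that projection is this package's choice of
how to place single nuclei into the well-level PC space). Feature rows are
centred and scaled to unit variance; zero-variance rows are dropped with a
warning; positional features (centroids, orientation) and border flags are
excluded. Missing cells are initialised to row means and refined by
iterating a rank-$k$ SVD reconstruction until the relative change falls
below $10^{-6}$ (cap 100 iterations, warning flag on non-convergence).
Component signs are fixed by making each component's largest-magnitude
loading positive. Prediction ellipses use the $\chi^2_2$ form: sample
covariance scaled by $\chi^2_2(p)\,(1 + 1/n)$, the documented choice for
"a new observation falls inside with probability $p$"; Monte-Carlo
coverage at $n = 200$ is 95% within one point.

## Entropy analysis

$H_0$ is the Shannon entropy, in bits, of one feature's values discretised
into 20 equal-width bins spanning the pooled finite range of *all compared
groups* (shared edges, recorded in the output). Groups are optionally
subsampled to the smallest group's size (seeded) so that $H_0$ differences
are not driven by sample-size bias; a Miller–Madow correction is available
but off by default. A constant feature has $H_0 = 0$; a feature uniform
over all bins attains $\log_2 20$. $\Delta H_0$ is the per-feature
difference between two groups (e.g. day 5 − day 0), compared across
features of a family with Wilcoxon signed-rank tests. Nuclei are pooled
across replicate wells within each (day, condition) group by default; this
pooling is configurable.

The base-2 logarithm and the discretisation scheme (equal-width, pooled
range, equal-$n$ subsampling) are this package's decisions; bits make
"one halving of distinguishable states" the unit.

## Rank tests

`compare_groups()` covers the designs used throughout: Mann–Whitney U
(two independent groups), Kruskal–Wallis with Dunn's pairwise z-tests and
Bonferroni correction over all $k(k-1)/2$ pairs, and the Wilcoxon
signed-rank test for paired designs. P-values are exact for small tie-free
samples, exact conditional permutation values for small samples with ties
(full enumeration for Mann–Whitney; a sign-flip count distribution over
doubled midranks for the signed-rank test), and normal approximations with
tie and continuity corrections otherwise. This keeps small-sample results
exactly reproducible by enumeration while remaining fast at scale.

# What the simulator emulates — and what it does not

`sim_config()` / `simulate_timecourse()` generate seeded two-channel
z-stacks with ground truth. The defaults are the study conditions and are
not tuned per analysis:

* field 512$\times$512 px at 0.108 µm/px, 8 z-planes (a desk-scale version
  of a 2560$\times$2160, 16-plane acquisition), ~30 nuclei per field,
  2 fields per well, 4 wells, days {0, 2, 5};
* elliptical nuclei with log-normal semi-axes (median 14 px, area
  roughly 400–900 px, comfortably inside the 200–5000 px filters);
* chromocenter-like Gaussian blobs ($\sigma \approx 2.5$ px, 4–10 per
  nucleus) whose contrast grows over days (0.6 → 1.0 → 1.4), emulating
  heterochromatin re-aggregation during culture;
* a GFP channel equal to the RFP spatial pattern times a per-nucleus
  ratio — both markers are chromatin-bound, and the analysed statistic is
  the mean-intensity ratio, so co-localisation is the right level of
  detail (no H1 binding kinetics are modelled);
* a ratio schedule declining 1.0 → 0.55 → 0.3 with CV 0.2, the hallmark
  linker-histone decline;
* a per-day heterogeneity multiplier (1.0 → 0.75 → 0.5) scaling the
  population SDs of shape/texture parameters — the entropy-decline ground
  truth;
* mis-segmentation distractors at Poisson rates per field: border-truncated
  nuclei, overlapping merged pairs, and dim elongated debris;
* a smooth multiplicative illumination bias (amplitude 0.15) shared by all
  fields of an experiment, Gaussian focal weighting across z (peak
  normalised to 1, so max-projection of a noiseless stack recovers the
  in-focus image exactly), and Poisson shot noise (gain 200) plus Gaussian
  read noise (SD 0.01).

Not modelled: optical PSF blur, chloroplast autofluorescence,
photobleaching, cell movement between time points, or nucleus-free image
clutter beyond the debris class. Passing tests therefore demonstrate that
the *analysis chain* recovers planted population structure under realistic
noise, bias and mis-segmentation pressure — not that it is robust to every
optical artefact of a real microscope.

# Problem sizes used by the test-suite fixtures

The suite runs the full chain on a day-0/day-5 time course (4 wells
$\times$ 2 fields $\times$ 2 days, ~500 QC-passed nuclei) with the ratio
schedule 1.0 → 0.3 and heterogeneity halved at day 5; the QC benchmark
uses 10 dense fields (~1000 labelled objects, ~20% class B). These sizes
give stable statistics (ratio medians within a few percent, texture
$\Delta H_0$ hundreds of features deep) while keeping a full run in
minutes on one CPU.

# Known limitations

* The TAS thresholds and the Gabor parameterisation of the original
  high-content platform are not published; this package's choices are
  documented above and fixed, but numeric feature values are not expected
  to match that platform column-for-column. The registry *structure*
  (totals per family and channel) is exact.
* Entropy values depend on the binning scheme; comparisons are only
  meaningful within a fixed scheme (shared edges are recorded in every
  output row for that reason).
* The $\chi^2$ prediction-ellipse form slightly undercovers at very small
  $n$ (it ignores the Student-$t$ widening); at the well counts used here
  the effect is within the stated $\pm 1$ point.
* Segmentation deliberately has no watershed splitting; heavily confluent
  cultures would shift load onto the QC classifier.

# A minimal session

```{r example}
library(chromaphen)

cfg <- sim_config(days = c(0L, 5L), ratio_mean = c(1.0, 0.3),
                  heterogeneity_scale = c(1.0, 0.5),
                  chromocenter_contrast = c(0.6, 1.4))
res <- run_pipeline(pipeline_config(sim = cfg))

# linker-histone decline
tapply(res$features$ratio, res$features$day, median, na.rm = TRUE)

# PC separation of culture days
print(res$pca$pca)

# entropy decline of texture features
family_entropy_comparison(res$entropy$differential, family = "texture")
```
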