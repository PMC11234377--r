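# chromaphen

High-throughput chromatin phenotyping of plant nuclei from two-channel
fluorescence microscopy.

Cultured protoplasts — wall-free plant cells that can be reprogrammed
towards pluripotency in vitro — reorganise their chromatin within the first
days of culture. `chromaphen` is for researchers who image such cultures
with two chromatin reporters (a core nucleosome marker such as H2B–RFP for
"total chromatin", and a linker histone marker such as H1.2–GFP) and want
reproducible, single-nucleus quantification of three things:

1. **Linker-histone abundance**: the per-nucleus background-subtracted
   intensity ratio GFP/RFP and its decline over culturing days;
2. **Morphology and chromatin texture**: a 370-feature registry per nucleus
   (16 shared morphology features + 177 per channel: 12 intensity
   statistics, 7 Hu moment invariants, 4 Gabor responses, 54 threshold
   adjacency statistics, 100 local binary pattern values over radii 1–10),
   summarised by PCA with SVD imputation, 95% prediction ellipses, density
   maps and correlation-clustered heatmaps;
3. **Population heterogeneity**: the discretised Shannon entropy of each
   feature across nuclei, H0 = −Σᵢ pᵢ log₂ pᵢ over 20 shared-edge bins,
   and its change ΔH0 = H0(day 5) − H0(day 0) per feature, compared across
   feature families and culture conditions with Wilcoxon signed-rank tests.

The package also contains the full upstream pipeline: a seeded synthetic
image simulator with ground truth (elliptical nuclei with chromocenter
blobs, day-dependent GFP:RFP ratio and heterogeneity schedules, truncated /
merged / debris distractors, illumination bias, Poisson + Gaussian noise),
maximum-intensity projection, retrospective illumination correction,
ranged-Otsu segmentation (smooth → threshold → fill holes → drop objects
< 200 px → 8-connected labels → border flags), and an RBF-SVM segmentation
quality control on 7 object features followed by a strict > 5000 px
giant-nucleus filter.

## Worked example

Simulate a day-0 vs day-5 time course (4 wells × 2 fields per day) in which
the true GFP:RFP ratio declines 1.0 → 0.3 and the population heterogeneity
of shape/texture parameters is halved at day 5, then run the full pipeline:

```r
library(chromaphen)

cfg <- sim_config(days = c(0L, 5L), ratio_mean = c(1.0, 0.3),
                  heterogeneity_scale = c(1.0, 0.5),
                  chromocenter_contrast = c(0.6, 1.4))
res <- run_pipeline(pipeline_config(sim = cfg))

tapply(res$features$ratio, res$features$day, median, na.rm = TRUE)
#>         0         5
#> 0.9958186 0.2895066
```

The planted ratio decline is recovered within a few percent (the residual
comes from shot noise and background subtraction). QC kept 494 of 546
segmented objects (52 SVM rejections, 0 giants). The well-median PCA
separates the days on PC1:

```r
print(res$pca$pca)
#> PCA (SVD with imputation): 363 features, 8 samples
#>   variance explained: PC1 69.1%, PC2 8.5%
```

with day-0 wells at PC1 ≈ +6.6 to +18.5 and day-5 wells at PC1 ≈ −12.6 to
−15.4 — disjoint 95% prediction ellipses. The halved heterogeneity shows up
as an entropy decline concentrated in the texture family:

```r
family_entropy_comparison(res$entropy$differential, family = "texture")
#> Wilcoxon signed-rank (dH0 vs 0): statistic = 1548, p = 4.64e-50
#>   n: A=330
```

with median texture ΔH0 = −0.56 bits. Group contrasts
(`compare_groups()`) cover Mann–Whitney U, Kruskal–Wallis + Dunn +
Bonferroni and paired Wilcoxon designs; `positive_fraction()` scores
detectable-signal percentages; `pearson_feature_corr()` reports per-group
feature correlations.

See the methods vignette (`vignettes/chromatin-phenotyping.Rmd`) for the
model behind every stage, the simulator's assumptions, and all numerical
choices.

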