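# octaperf

Quantifies capillary non-perfusion in en face OCT angiography (OCTA)
projections, for researchers comparing perfusion biomarkers in diseases such
as glaucoma that reduce retinal capillary perfusion.

## The idea

The classic OCTA biomarker, **vessel density** (VD = fraction of vessel
pixels), is robust but insensitive to early capillary loss. Measures of the
spaces *between* vessels — **intercapillary areas** (IA, connected
components of the inverted vessel mask) — are sensitive but fragile: one
small gap in the segmentation merges two lacunae into one region with
roughly double the area, distorting every area statistic.

This package implements the more robust alternative: from a binary vessel
mask it computes the **perfusion distance** map

> d(p) = min over vessel pixels v of ||p − v||  (exact Euclidean distance
> transform),

thresholds it at a distance t (default 30 µm, converted by the pixel pitch)
to obtain **perfusion deficit areas** (PDA = connected components of
{p : d(p) > t}), and summarises the distribution of their areas by its
maximum, mean, standard deviation and (excess) kurtosis. Because distances
change only marginally when a small segmentation gap opens, these features
keep the sensitivity of area-based measures without their fragility.

It also provides the competing handcrafted biomarkers —

| method | features |
|---|---|
| VD | vessel-pixel fraction (1) |
| GPDP | deficit-pixel fraction of the reference area (1) |
| IA | max, mean, std, kurtosis of intercapillary areas (4) |
| PD | max, mean, std, kurtosis of perfusion distances (4) |
| PDA | max, mean, std, kurtosis of deficit areas (4) |

— a classical segmentation front end (histogram matching, CLAHE, multi-scale
Frangi vesselness, hysteresis thresholding, morphological cleanup), a
patient-grouped five-fold SVM cross-validation harness (AUROC / F1), and a
synthetic capillary-network generator with ground-truth masks so the whole
pipeline is testable without clinical data.

## Worked example

```r
library(octaperf)

# a synthetic two-class cohort: 15 control eyes, 15 eyes with 35% capillary
# dropout, written to disk with ground-truth masks and a manifest
dir <- file.path(tempdir(), "demo")
man <- generate_cohort(15, 15,
  params_control = synth_params(image_size = 256, seed = 0),
  params_case    = synth_params(image_size = 256, seed = 0, dropout_prob = 0.35),
  seed = 42, out_dir = dir)

# per-eye biomarkers on one case eye's ground-truth mask
m   <- read_mask(man$mask_path[16])
pdm <- perfusion_distance_map(m)
vessel_density(m)                                  # 0.2209015
gpdp(pdm, 30 / 5.7)                                # 0.1299896
pda_distribution_features(perfusion_deficit_areas(pdm, 30 / 5.7))
#>   maximum  mean standard_deviation kurtosis
#> 1     639  72.8               105.     10.1

# feature extraction + grouped SVM comparison for the whole cohort
run <- run_pipeline(man, use_truth_masks = TRUE)
glance(run)
#>   plexus method mean_auroc mean_f1 n_folds
#> 1 SVP    GPDP            1       1       5
#> 2 SVP    IA              1       1       5
#> 3 SVP    PD              1       1       5
#> 4 SVP    PDA             1       1       5
#> 5 SVP    VD              1       1       5
```

The case eye's deficit-area distribution is heavy-tailed (maximum 639 px vs
mean 72.8 px, excess kurtosis 10.1): capillary dropout creates a few very
large non-perfused regions, exactly the signal the PDA features summarise.
At this severe synthetic dropout every method separates the classes
perfectly; the interesting comparisons are the robustness properties (see
the vignette, e.g. `fixture_two_chamber()`: a 1-px segmentation gap changes
the maximum intercapillary area by ≥ 90 % while the mean perfusion distance
moves by < 10 %).

`autoplot(run$cv)` plots per-fold AUROCs; `plot_area_histogram()` and
`plot_distance_map()` display the deficit-area distribution and the
distance map. A thin command-line front end with `simulate` / `segment` /
`features` / `classify` / `run` / `fixtures` subcommands is installed at
`inst/cli/octa-perfusion.R`.

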