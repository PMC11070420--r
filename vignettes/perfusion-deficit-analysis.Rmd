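---
title: "Quantifying capillary non-perfusion in OCTA en face images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying capillary non-perfusion in OCTA en face images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

OCT angiography (OCTA) visualises perfused retinal vessels. Diseases such
as glaucoma reduce capillary perfusion, and the classic summary — vessel
density (VD), the fraction of vessel pixels — is often too blunt to pick up
early change. Measures built on the *spaces between* vessels are more
sensitive: when a capillary disappears, two intercapillary lacunae merge
and the local area statistics change a lot, while VD barely moves. The
catch is that intercapillary areas (IA) computed directly from a binary
segmentation inherit every segmentation error in the same exaggerated way.

This package implements a middle path: compute the *perfusion distance*
(the exact Euclidean distance from each pixel to its nearest vessel pixel),
threshold it to obtain *perfusion deficit areas* (PDA), and summarise the
distribution of deficit-area sizes by its maximum, mean, standard deviation
and kurtosis. Distances change only marginally when a small gap opens in
the segmentation, so these features keep the sensitivity of area-based
measures while shedding much of their fragility. Alongside the PDA features
the package computes the competing handcrafted biomarkers — VD, IA
distribution features, perfusion-distance (PD) distribution features, and
the geometric perfusion deficit percentage (GPDP, the deficit-pixel
fraction of a reference area) — and compares them with a patient-grouped
SVM cross-validation harness.

## Pipeline

```{r, eval = FALSE}
library(octaperf)

img  <- read_image("eye.png")                    # en face projection
pre  <- preprocess_image(img)                    # histogram match + CLAHE
mask <- segment_vessels(pre)                     # Frangi + hysteresis
pdm  <- perfusion_distance_map(mask)             # exact EDT
pda  <- perfusion_deficit_areas(pdm, 30 / 5.7)   # 30 um threshold
pda_distribution_features(pda)
```

`extract_features()` bundles all five feature families into a long tibble,
and `run_pipeline()` maps a cohort manifest through the whole chain and
into `cross_validate()`.

## Model and assumptions

**Segmentation.** A vessel mask is produced by histogram matching to a
reference image, CLAHE, a multi-scale Frangi vesselness filter, hysteresis
thresholding and morphological cleanup. Frangi assumes bright tubular
structures on a darker background (OCTA flow signal is bright). The
per-image maximum response is normalised to 1, so hysteresis thresholds are
relative to the strongest vessel in the image — this makes one threshold
pair usable across scans of different overall signal, which is the same
motivation as the histogram-matching step.

**Perfusion distance.** The distance map is the exact Euclidean distance
transform of the mask. Zero exactly on vessels, positive elsewhere — a
property the tests assert, since the PD features are computed over the
non-vessel pixels only (the zeros carried by vessel pixels describe the
mask, not the gaps between vessels; the distribution of interest is the
gap-width distribution).

**Deficit areas.** Pixels with distance strictly greater than the
threshold, grouped into connected components. At threshold zero this is
exactly the intercapillary partition, a useful consistency identity that
the tests assert for both connectivities.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `threshold_um` | 30 | µm | deficit threshold; ~half the normal intercapillary spacing, so healthy lacunae mostly stay below it |
| `pixel_pitch_um` | 5.7 | µm/px | lateral sampling of 3×3 mm macular scans on a 512 grid |
| `frangi_scales` | 1, 1.5, 2 | px | capillaries are ≈1–2 px wide at this pitch |
| `frangi_beta`, `frangi_gamma` | 0.5, 15 | — | classic sensitivity constants; γ on a 0–255 intensity footing |
| `hyst_low`, `hyst_high` | 0.05, 0.15 | — | on normalised vesselness; calibrated once on the canonical synthetic reference |
| `connectivity` | 8 | — | dark lacunae treated as diagonally continuous |
| `clip_limit` | 0.01 | — | CLAHE clip as a fraction of the tile histogram |

The deficit threshold is configured in micrometres and converted by
`threshold_um / pixel_pitch_um`, so results are comparable across scan
protocols. Binarisation is strict (`distance > threshold`).

**Conventions fixed for reproducibility.** Distribution features use
population (biased) moments and Fisher excess kurtosis (normal ⇒ 0).
Degenerate inputs — zero or one region, zero variance — yield 0 for the
undefined statistics, with a warning, so SVM feature vectors stay finite.
Regions touching the image border are included by default
(`exclude_border_regions` is available). Pixel indices are 1-based with
pixel centres on the integer grid; areas are reported in pixels, with a
µm² conversion in `tidy()` output.

## The synthetic cohort generator

The study-scale clinical data that motivates this package is not publicly
available, so the package ships a synthetic generator that every stage is
tested against:

1. **Junctions** are placed by Poisson-disc sampling at a minimum spacing
   of 12 px (~68 µm, a typical macular intercapillary scale).
2. **Capillaries** connect junctions via the Gabriel graph (edges longer
   than 2× the spacing pruned). The Gabriel graph was chosen because it is
   a planar proximity graph that contains the Euclidean minimum spanning
   tree — so the healthy network is connected by construction — and its
   polygonal lacunae visually resemble en face capillary meshes. No claim
   of biophysical realism is made.
3. **Dropout** removes each edge i.i.d. with probability `dropout_prob`,
   the severity knob standing in for diffuse glaucomatous capillary loss.
   A clustered-dropout option exists but is off by default. The literature
   gives no quantitative capillary-loss fraction per disease stage, so the
   knob is deliberately uncalibrated to disease grade.
4. **Rendering** rasterises alive centrelines with a Gaussian profile
   (σ = 1 px, i.e. ~11 µm-wide vessels), adds a dim background floor
   (0.08) and multiplies by gamma-distributed speckle with coefficient of
   variation `noise_level` (default 0.4 — OCTA images are strongly
   speckled). The ground-truth mask is exactly the σ-tube around alive
   centrelines, verified against a brute-force point-to-segment oracle.
5. **Cohorts** group eyes into patients at ~1.4 eyes/patient so that
   patient-grouped splitting is genuinely exercised. Two eyes of a patient
   get independent seeds; intra-patient correlation is not modelled — the
   split scheme tests grouping logic, not correlation structure.

**What the generator does not emulate:** OCTA acquisition physics
(decorrelation noise along vessels, projection and motion artifacts),
multi-plexus 3D geometry, and signal dropout *on* vessels. Its speckle is
multiplicative on an always-bright vessel profile, so segmentation of
synthetic images rarely shows the false *gaps* that clinical segmentations
show. Passing tests therefore demonstrate correctness of the machinery and
the direction of dropout effects, not clinical performance.

## Classification harness

Patients are shuffled (seeded), stratified by label, and dealt into five
folds; all eyes of a patient share a fold. Rotation `f` uses fold `f` as
test, fold `f %% k + 1` as validation and the rest as training (a 60/20/20
split in which each eye serves exactly once in validation and once in
test). Features are standardised with training-set statistics — SVMs are
scale-sensitive and the families mix fractions with pixel areas spanning
orders of magnitude. The grid (linear and RBF kernels, C ∈ {0.1, 1, 10,
100}, γ ∈ {1/(p·Var), 0.01, 0.1, 1}) is fixed and ordered so validation
ties resolve deterministically; the grid point with the best validation
AUROC is evaluated once on the test fold. AUROC uses decision-function
margins with ties at ½ (Mann–Whitney); F1 uses hard predictions at the
default boundary.

## Problem sizes used in the shipped checks

Unit tests run on 128–256 px images and 32×32 random masks against
brute-force oracles (exact EDT equivalence, pairwise-enumeration AUROC,
hand-computed moments). The end-to-end comparison runs five independent
60-vs-60-eye cohorts at the full 512 px defaults with dropout 0.35 for the
case class — small by clinical standards but large enough for stable fold
metrics; the same conditions are recomputed by `scripts/acceptance.R`.

## Known limitations

- At severe synthetic dropout (0.35) on clean synthetic vasculature, *all*
  five feature families separate the classes almost perfectly (AUROC ≳
  0.99), so the clinical *ranking* of methods — where IA is degraded by
  real segmentation gaps — is compressed into ceiling effects and should
  not be read off synthetic cohorts. The direction-of-effect properties
  (deficit areas grow with dropout; a 1-px wall gap upends IA statistics
  while moving mean perfusion distance by <10%) are the meaningful
  synthetic checks.
- The robustness fixture (`fixture_two_chamber()`) is a stylised geometry,
  not a capillary network.
- Segmentation quality on clinical scans depends on parameters this
  package cannot calibrate without clinical data; the defaults were fixed
  once against the canonical synthetic reference and are verified by the
  tests to exceed Dice 0.7 with full sensitivity on noise-free synthetic
  images.
- The SVM harness assumes exactly two classes and one label per patient.

## Reproducing the shipped numbers

`scripts/acceptance.R --seed S --out results.json` regenerates a 60/60
cohort from seed `S`, runs the full algorithmic pipeline and writes the
per-method mean AUROC/F1 plus per-class VD and GPDP means as JSON. The
README shows one run's output.
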