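# exmtools

Quantitative image analysis for multiplexed ion-count imaging (MIBI / IMC)
of physically expanded tissue gels.

Hydrogel expansion magnifies tissue ~3.7-fold before mass-spectrometry
imaging, pushing 400–1000 nm beam resolutions into the subcellular range.
For whoever runs that workflow — or wants to validate an analysis of it —
this package implements the downstream quantification:

* **Anchoring analysis** (the core): a layer-by-layer walk around each
  segmented vessel object. Ring `+k` is the k-th one-pixel shell outside
  the object (`D_k \ D_{k−1}` under unit dilation), ring `−k` the k-th
  shell inside (`E_{k−1} \ E_k` under unit erosion); there is no step 0.
  Rings overlapping other vessels are excluded; per step the mean count of
  every marker and the pixel fraction of every phenotype/feature class are
  collected per vessel, square-root transformed, averaged across vessels
  with 95% CIs, z-normalised per channel across steps, and each channel's
  peak step localised. Around brain vessels this resolves the layered
  organisation of the blood–brain barrier (lumen leakage markers →
  endothelium → basement membrane → astrocyte end-feet → microglia).
* **Expansion-fold estimation** by three concordant strategies: mean of
  pairwise landmark-distance ratios (± SD), √(tissue-area ratio), and
  √(cell-size-distribution ratio).
* **Resolution** by the 16–84% edge-spread criterion on line scans
  (distance over which an edge rises from 16% to 84% of its amplitude;
  2σ for a Gaussian edge).
* **Distortion**: rolling-ball background subtraction, affine + nonrigid
  registration of paired images, and the RMS of pairwise feature-distance
  changes binned by measurement length (12.15 µm × 100 bins), mean ± SD
  across replicate regions.
* **Feature segmentation** from weighted channel composites
  (blur → Otsu/absolute threshold → closing → 8-connected labelling →
  size filter), per-cell quantification, percentile capping (99.7 default)
  and dsDNA-median tile normalisation.
* **Axis gradients**: perpendicular sums along a tissue strip, 5%/95%
  quantile min-max normalisation, 200-px windows sliding by 50 px with CIs.
* **Synthetic phantoms** with analytic ground truth for all of the above:
  vessels with concentric marker layers at known signed radial offsets,
  nuclear cell fields, Poisson count noise, known rescalings and known
  smooth warp fields.

Images travel as directories of single-channel grayscale TIFFs plus a
panel CSV and a JSON metadata file; the package includes its own minimal
uncompressed-TIFF reader/writer and Rcpp implementations of the raster
primitives (morphology, exact Euclidean distance transform, connected
components).

## Worked example

Two synthetic vessels carry four markers at signed radial offsets −10
(inside the vessel object, toward the lumen), 0, +3 and +8 px; channels
are Poisson ion counts (amplitude 50 over background 1). Profile, aggregate
and localise peaks:

```r
library(exmtools)
layers <- list(
  list(marker = "SAA",        offset_px = -10, thickness_px = 2, amplitude = 50),
  list(marker = "GLUT1",      offset_px = 0,   thickness_px = 2, amplitude = 50),
  list(marker = "CollagenIV", offset_px = 3,   thickness_px = 2, amplitude = 50),
  list(marker = "GlnSyn",     offset_px = 8,   thickness_px = 2, amplitude = 50))
vessels <- list(
  list(center = c(100, 100), lumen_radius_px = 12, wall_thickness_px = 4),
  list(center = c(100, 220), lumen_radius_px = 12, wall_thickness_px = 4))
sp <- phantom_spec(320, 320, vessels = vessels, layers = layers,
                   background_rate = 1, seed = 1)
ph <- make_vessel_phantom(sp, poisson = TRUE)
pv <- profile_vessels(ph$image, ph$mask, k_min = -14, k_max = 14, se = "disc")
hp <- heatmap_and_peaks(aggregate_profiles(pv))
hp$peaks
#>     variable peak_step
#> 1        SAA       -10
#> 2      GLUT1         1
#> 3 CollagenIV         3
#> 4     GlnSyn         9
```

The recovered peak steps reproduce the generative radial ordering exactly
(SAA inside the object, GLUT1 at the boundary, CollagenIV then GlnSyn
outside; Kendall tau = 1 against the true offsets). With Poisson noise a
peak can land on the neighbouring ring of an exact geometric tie — GlnSyn's
annulus covers rings 8 and 9 completely, so either is a faithful argmax;
noise-free profiles recover −10, −1 (offset 0 has no step 0), +3, +8
exactly. The aggregated profile carries the per-step statistics behind the
peaks, e.g. for GlnSyn (sqrt-transformed means ± 95% CI across vessels):

```r
subset(as.data.frame(aggregate_profiles(pv)),
       variable == "GlnSyn" & step >= 6 & step <= 10)
#>     step variable  mean     sd n ci_lo ci_hi
#> 104    6   GlnSyn 0.959 0.0645 2 0.869  1.05
#> 105    7   GlnSyn 3.102 0.0276 2 3.063  3.14
#> 106    8   GlnSyn 7.068 0.0332 2 7.022  7.11
#> 107    9   GlnSyn 7.075 0.0871 2 6.954  7.20
#> 108   10   GlnSyn 0.997 0.0169 2 0.974  1.02
```

√50 ≈ 7.07 on the annulus rings, √1 ≈ 1 off them — the sqrt-transformed
amplitude and background, as constructed.

## Analysis workflow

The numbered drivers under `analysis/` run the full pipeline end to end and
write their tables under `results/`:

1. `01_simulate.R` — phantom FOVs (vessels + cell fields) with ground truth
2. `02_expansion_fold.R` — the three fold estimators on a 3.7× pair
3. `03_resolution.R` — 16–84% line-scan resolution, 5 scans per condition
4. `04_distortion.R` — warp → register → RMS-vs-length curves, 3 replicates
5. `05_anchoring.R` — segmentation + anchoring on the simulated vessels
6. `06_gradient.R` — gray/white-matter style gradient windows

Run them in order with `Rscript analysis/01_simulate.R` etc.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main results from scratch at the given seed —
anchoring peak recovery on a 36-vessel phantom, the three expansion-fold
estimators against a known 3.7× scaling, and the 16–84% resolution of a
σ = 2 px Gaussian edge — and writes the JSON target report to `--out`.
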