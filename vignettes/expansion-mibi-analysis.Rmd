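---
title: "Quantitative analysis of expansion-gel multiplexed ion-beam images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of expansion-gel multiplexed ion-beam images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exmtools)
```

## The problem this package addresses

Multiplexed ion-beam imaging (MIBI) and imaging mass cytometry (IMC) record
ion counts of lanthanide-tagged antibodies per pixel, with 20+ channels per
field of view but a spatial resolution limited by the beam or laser spot
(roughly 0.4–1 µm). Physically expanding the tissue in a hydrogel before
imaging (~3.7-fold laterally, with the expanded gel dried and compressed so
it survives the vacuum chamber) pushes the effective resolution into the
subcellular range. That workflow creates a set of quantitative questions
that this package answers on ion-count images:

* **How much did the sample expand?** Three independent estimators of the
  linear expansion fold (landmark distances, tissue areas, cell-size
  distributions) that should agree with each other.
* **What resolution was achieved?** Edge-spread analysis of line scans via
  the 16–84% criterion.
* **How distorted is the gel?** RMS change of pairwise feature distances
  versus measurement length, after affine + nonrigid alignment of paired
  images.
* **How are molecules organised around a structure?** The anchoring
  analysis: one-pixel morphological step rings walked inward and outward
  from segmented vessel objects, with per-step marker statistics — used to
  resolve the layered organisation of the blood–brain barrier (endothelium,
  basement membrane, astrocyte end-feet, perivascular microglia).

Every analysis is exercised on synthetic phantoms with known ground truth;
the package contains the generator as first-class, tested code.

## Containers and conventions

Images are named lists of non-negative matrices (`multiplex_image`), with a
physical pixel size (µm/px of the acquired grid) and an `expansion_fold`
annotation. Coordinates are (row, col), 0-based, pixel centres at integers.
Physical distances are pixel distances × pixel size; *pre-expansion*
distances are additionally divided by the expansion fold, which is the
scale-bar convention for expanded samples. On disk a field of view is a
directory of single-channel grayscale TIFFs plus `panel.csv` and
`fov.json`; the package carries its own minimal reader/writer for
uncompressed grayscale TIFF because this environment provides no image I/O
package.

## The anchoring model

Given a labelled vessel mask, step ring `+k` is the k-th one-pixel shell
outside the object (`D_k \ D_{k-1}` for k-fold unit dilation) and `-k` the
k-th shell inside it (`E_{k-1} \ E_k`). Step 0 does not exist: the object
interior is fully covered by the negative steps and the exterior by the
positive ones, which the tests assert exactly. Ring pixels overlapping any
*other* (non-dilated) object are removed so neighbouring vessels do not
contaminate each other. Per step, each vessel contributes its mean count
per channel and its class-pixel fractions; per-vessel values are
square-root transformed (a display convention for counts), averaged across
vessels, and reported with 95% confidence intervals. For the heatmap the
aggregated means are z-normalised per channel across steps (population SD),
and each channel's peak step is the argmax.

Choices the ring walk leaves open, and what this package does:

* **Structuring element.** The default is the 3×3 square, so the step index
  is the chessboard distance — the convention of MATLAB-style
  `imdilate`/`imerode` loops. A `"cross"` (city-block) element and a
  `"disc"` element are also provided. The disc variant steps by exact
  Euclidean distance (ring `+k` = pixels at outside distance in `(k−1, k]`,
  computed by distance transform, which defines the same sets as dilation
  by growing discs). It exists because the phantom generator lays marker
  annuli out in *Euclidean* signed distance: with chessboard rings an
  annulus at Euclidean offset +8 necessarily peaks at a smaller step (a
  chessboard shell contains pixels at Euclidean distances up to k·√2), so
  only the metric-matched disc stepping can recover layer offsets exactly
  in step index. On real data the choice matters little for ordering;
  for phantom validation it is the difference between exact and
  approximate recovery.
* **Replicate unit.** Aggregation averages per-vessel means rather than
  pooled pixels — each vessel is one biological replicate; a pooled mode
  would weight large vessels more. CIs are normal-approximation
  `mean ± 1.96·SE` across vessels by default, with a t-quantile mode
  behind a flag; at a typical n of 30+ vessels the difference is small,
  and the coverage test shows ≥93% empirical coverage at the nominal 95%.
* **Transform order.** sqrt per vessel, then mean, then z — matching the
  stated sequence of the display convention.
* **Peak ties.** An annulus centred at integer offset `o` (thickness 2)
  covers rings `o` and `o+1` completely, an exact tie. Ties therefore
  break toward the smallest `|k|` (the boundary) first, then toward the
  lumen; this returns `o` itself for every nonzero offset. A layer at
  offset 0 has no step 0 to land on and resolves to −1. Breaking ties
  toward the lumen alone (the other natural rule) would systematically
  report one step inside the annulus centre, which is why it is not the
  default.
* **Border handling.** Pixels outside the image count as background, so
  rings clip at borders; vessels whose `k_max`-dilation would leave the
  image are excluded from aggregation by default (their truncated outer
  rings would bias means toward the image interior).

## The synthetic world

`make_vessel_phantom()` draws circular vessel cross-sections (lumen disc
dilated by a wall) and paints each marker at `amplitude` expected counts on
the annulus of signed Euclidean boundary distance `offset ± thickness/2`,
measured from the discretised object mask by distance transform — the same
geometry the disc-stepping rings measure, so generator and analysis share
one convention. Channels are Poisson-sampled when requested: MIBI channels
are raw ion counts, and pure Poisson (no detector dead-time) is the noise
model throughout. Defaults are chosen to resemble expanded brain FOVs:
0.39 µm pixels, vessel objects ~16 px radius, layer amplitudes of ~50
counts over a background of ~1 count, 30+ vessels per analysis. The radial
layout itself (offsets −10, 0, +3, +8 for the leakage marker, endothelial
boundary, basement membrane and astrocyte end-feet stand-ins) is a free
choice: no quantitative radial layout is published for the BBB layers, so
recovery is judged against the generator's own truth, primarily as
*ordering* (Kendall tau).

`make_cell_field()` places non-overlapping circular cells with lognormal
areas by rejection sampling; `apply_scale()` rescales images or masks by a
known fold (the `expansion_fold` annotation multiplies; label masks use
nearest-neighbour so identities survive); `make_smooth_warp()` interpolates
random control-point offsets with tensor-product natural cubic splines and
rescales the dense field so its maximum displacement magnitude respects the
requested amplitude.

What a green test on this world does **not** establish: phantoms have
circular vessels, spatially uniform backgrounds, and independent Poisson
noise — real tissue has elongated and branching vessels, structured
background, channel spillover and segmentation errors. The 05 analysis
script shows one consequence deliberately: segmenting vessels from blurred
composites places the boundary a few pixels outside the generative one,
shifting absolute peak steps inward while preserving the radial ordering.
Conclusions from this package on real data should therefore lean on
orderings and differences, not absolute step indices.

## Expansion folds, resolution, gradients

The three fold estimators are reported on one comparable linear axis: the
linear estimator averages post/pre ratios over all landmark pairs (mean ±
SD); the area and segmentation estimators take the **square root** of
physical area ratios (tissue area, or the median/mean of per-cell areas).
The square root is a dimensional-consistency choice this package fixes
explicitly, since "ratio of areas" alone would sit on a quadratic axis.
Concordance of the three within 5% at folds 2.0–4.5 is an acceptance
criterion.

Line scans sample a channel at unit-pixel spacing with bilinear
interpolation (nearest-pixel behind a flag), positions reported in
pre-expansion µm. The 16–84% resolution criterion estimates the two
plateaus of an edge profile as the means of the first and last 10% of
samples (config-exposed; the criterion's source does not specify plateau
estimation), finds the 16% and 84% crossings by linear interpolation and
reports their distance: 2σ for a Gaussian-blurred edge, 0.68·L for a linear
ramp of length L. Non-monotone or plateau-free profiles error, naming the
failed check. The estimate is invariant to affine intensity transforms.

Tissue-strip gradients sum channels perpendicular to the long axis,
min-max normalise per channel between the 5% and 95% quantiles (values
outside [0, 1] are kept, not clipped), and average in 200-px windows
sliding by 50 px. The 95% CI within a window is computed across the
window's pixel lines — the replicate unit is not stated in the source
convention, so the across-positions choice is ours, with an across-tile
mode left to the caller by aggregating window tables.

## Distortion quantification

Paired images (e.g. pre- vs post-compression overviews) are background
subtracted with a rolling ball (grayscale opening by a disc, default
radius 50 px), aligned by a full 6-parameter affine minimising mean squared
intensity difference over a multi-resolution pyramid (Nelder-Mead), then by
a nonrigid stage: block matching on a control grid against the
affine-aligned image (integer search, quadratic subpixel refinement, three
refinement iterations), interpolated to a dense field by the same
tensor-product splines the generator uses, with control nodes extended to
the image border so the field never extrapolates. An externally computed
displacement field can be supplied in place of estimation.

Distortion is the RMS of pairwise distance changes: for every unordered
landmark pair, `e = |L − L'|` between reference distances and distances
after the correspondence mapping, binned by `L` (12.15 µm bins, 100 bins by
default) and aggregated across replicate regions as mean ± SD. Absolute
distance change (not vector displacement) is used, matching the
measurement-length convention of the expansion-microscopy literature. Two
conventions matter and are both exposed:

* `map_landmarks(lm, reg$field)` measures the *residual* distortion after
  the affine stage has removed global pose and scale — the quantity a
  distortion curve reports on real data.
* `transform_landmarks(reg, lm)` maps through the *full* composed
  transform. This is the right object to compare against a known
  generative warp, because the affine stage legitimately absorbs whatever
  net affine component a random smooth warp contains; comparing the
  residual field against the raw generative field would mix that
  bookkeeping into the science. The end-to-end test requires the full
  pipeline's curve to track the ground-truth-field curve within 20% at
  warp amplitudes 1–5 px, and to stay below 0.3 px with no warp.

## Numerical choices and degenerate inputs

* Percentile capping (default 99.7 per channel) and quantile min-max use
  linear interpolation between order statistics (R's type 7); the test
  oracles use the same stated convention. Capping is idempotent only up to
  the interpolation at the cap (~1e−6 relative), because flattening the
  tail moves the interpolated order statistic slightly.
* dsDNA tile normalisation divides every channel by the median of the
  *nonzero* dsDNA pixels: ion-count channels are zero-inflated and an
  all-pixel median can be 0. All-zero (or <1% nonzero) dsDNA errors.
* Otsu thresholds maximise between-class variance over 256 equal-width
  bins; segmentation is invariant to positive rescaling of the composite.
* Connected components are 8-connected; labels are consecutive in reading
  order of each object's first pixel. Objects below `min_size_px` are
  dropped before relabelling.
* The Euclidean distance transform is the exact two-pass
  Felzenszwalb–Huttenlocher algorithm; unreachable sites use a large
  finite sentinel internally to keep the parabola arithmetic finite.
* Empty rings yield `NA` statistics (never silent zeros); empty
  segmentation foreground yields an empty mask with a message, not an
  error; aggregation with zero objects errors.
* Registration errors out (with the loss trajectory) if the fitted affine
  is worse than identity at full resolution.

## Known limitations

* Vessels are profiled as 2-D cross-sections; there is no 3-D anchoring.
* The registration is a deliberately simple SSD optimiser adequate for
  smooth, well-textured overview images; it is not a replacement for a
  full deformable-registration tool, and accepts external fields for that
  reason.
* The argmax phenotyper is plumbing that stands in for cluster-based
  phenotyping (out of scope); it is deterministic and documented, not
  biologically serious.
* Statistical comparison between sample groups (e.g. diseased vs control)
  is out of scope; the anchoring output is descriptive.

## A minimal session

```{r example, eval = FALSE}
layers <- list(
  list(marker = "SAA", offset_px = -10, thickness_px = 2, amplitude = 50),
  list(marker = "GLUT1", offset_px = 0, thickness_px = 2, amplitude = 50),
  list(marker = "CollagenIV", offset_px = 3, thickness_px = 2, amplitude = 50),
  list(marker = "GlnSyn", offset_px = 8, thickness_px = 2, amplitude = 50))
vessels <- list(list(center = c(100, 100), lumen_radius_px = 12,
                     wall_thickness_px = 4),
                list(center = c(100, 220), lumen_radius_px = 12,
                     wall_thickness_px = 4))
sp <- phantom_spec(320, 320, vessels = vessels, layers = layers,
                   background_rate = 1, seed = 1)
ph <- make_vessel_phantom(sp, poisson = TRUE)
pv <- profile_vessels(ph$image, ph$mask, k_min = -14, k_max = 14,
                      se = "disc")
hp <- heatmap_and_peaks(aggregate_profiles(pv))
hp$peaks
```

The numbered scripts under `analysis/` run the full workflow (simulation,
folds, resolution, distortion, anchoring, gradients) and write their tables
under `results/`.
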