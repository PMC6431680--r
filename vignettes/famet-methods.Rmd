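---
title: "Methods: single-cell focal adhesion metrology and confinement-state classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell focal adhesion metrology and confinement-state classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famet)
```

# The problem

Adherent cells read the geometry of their substrate and respond by
changing shape. On flat glass a fibroblast spreads into an elongated,
ellipse-like lamella; confined inside the triangular pores of a
precision-woven microfiber scaffold, the same cell becomes small,
triangular and concave, and reorganizes its vinculin-rich focal
adhesions (FAs) from a body-wide carpet of elongated streaks into a few
large, rounded, perinuclear clusters. `famet` is a metrology toolbox
for exactly this readout: it turns calibrated 3-channel fluorescence
images (red = actin, green = vinculin, blue = nucleus) into a 7-feature
quantitative description of the single cell, and classifies the
*confinement state* of each cell with a cross-validated linear SVM.

Four archetypal confinement states are used throughout, labeled A-D:

| class | substrate context | morphology |
|---|---|---|
| A | flat, unconfined | elongated ellipse, body-wide elongated FAs |
| B | sparse random fiber mesh | high-variance mixture of lamellar shapes |
| C | dense random fiber mesh | small, poorly spread, few FAs |
| D | woven 3D micro-pores | concave triangle, large perinuclear FA clusters |

# The segmentation workflow

Every channel is reduced to a 2D image by **maximum intensity
projection**, then segmented by a fixed sequence:

1. linear min-max rescale to [0, 1] (the 8-bit normalization
   convention);
2. **CLAHE** — contrast-limited adaptive histogram equalization
   (default 8 x 8 tiles, clip factor 2);
3. **non-local-means denoising** — edge-preserving patch averaging
   (patch 5 px, search window 11 px, strength 0.8 x a robust noise
   estimate unless set explicitly). Implemented in C++ with one
   summed-area table per search offset, so cost is independent of patch
   size;
4. **Otsu thresholding** over 256 gray levels (foreground strictly
   above the level maximizing between-class variance);
5. **conditional erosion** — one synchronous pass removing every
   foreground pixel with at least `erosion_neighbor_threshold` (default
   5) background pixels among its 8 neighbours. Out-of-image pixels
   count as background;
6. **hole filling** — background components not connected to the image
   border become foreground.

For the cell body (red) and nucleus (blue) the largest connected
component is kept (single-cell fields are assumed). For FAs (green) an
extra **dilation** (disc, radius 1 px) is inserted before the erosion
to consolidate fragmented puncta, and connected components (8-connected
by default, so thin diagonal adhesions are not split) are triaged by
area: below 0.1 µm² = cytosolic background (excluded from all metrics),
0.1-0.2 µm² = nascent adhesion, **at or above 0.2 µm² = mature FA**.
Only mature FAs enter the downstream metrics. Components that do not
touch the cell mask dilated by 2 px are discarded; adhesions sit at the
cell periphery, where the two masks can disagree by a pixel.

Two conventions deserve a note. First, all masks are foreground = TRUE;
black/white inversion in the source material is a rendering convention
with no computational content. Second, the maturity boundary is
inclusive: a component of exactly 0.2 µm² is mature.

# The metrics

With `m00` the mask area and `mu20`, `mu02`, `mu11` its central second
moments (pixels treated as unit squares, i.e. a 1/12 per-pixel
second-moment correction, which makes rasterized analytic shapes agree
with their continuous moments):

* **Cell area (III)** — foreground pixel count x pixel_size².
* **Ellipticity (I)** — from the affine moment invariant
  `J = (mu20*mu02 - mu11^2)/m00^4`: `16*pi^2*J` if `J <= 1/(16*pi^2)`,
  else `1/(16*pi^2*J)`. Equal to 1 for every perfect ellipse; a filled
  square scores `9/pi^2 ≈ 0.912`; invariant to rotation and scale.
* **Rectangularity (II)** — area over the *axis-aligned* bounding-box
  area. Deliberately not rotation-invariant: the bounding box is read
  along image x/y, so a rotated rectangle scores below 1. We keep this
  axis-aligned convention (rather than the rotated minimum-area
  rectangle) because the bounding box is defined by the x- and
  y-direction extents of the feature.
* **Solidity** (auxiliary) — area over convex-hull area, the hull taken
  over pixel corners; low values flag concave, "ruffled" outlines.
* **FA size (IV)** and **FA aspect ratio (V)** — per-cell *means* over
  mature FAs of component area and of the major/minor axis ratio of the
  moment-equivalent ellipse. The per-cell reduction to the mean is a
  package choice; single-pixel or collinear components get a minor axis
  floored at one pixel width and are flagged.
* **E-slope (VI)** — the E-function is the empirical cumulative
  distribution of FA-centroid-to-nucleus-centroid distances, evaluated
  at its n step points `(d_(i), i/n)` with no binning or interpolation.
  A straight line constrained through the origin is fitted by least
  squares; the slope is `sum(d_i f_i) / sum(d_i^2)` (units 1/µm). The
  y-axis is normalized to cumulative *fraction* so slopes are
  comparable across cells with different FA counts. High slope =
  perinuclear concentration.
* **G-function (VII)** — mean nearest-neighbour distance between mature
  FA centroids (exact all-pairs; ties are unproblematic because the
  value, not the identity, of the nearest neighbour is used). Low =
  clustered.

Distances are measured in the 2D projection plane, in µm, with 0-based
pixel indices, origin top-left, x rightward, y downward. Cells with
fewer than one (IV, V, VI) or two (VII) mature FAs get missing entries,
a QC flag, and are dropped from classification rather than imputed.
Solidity, FA count and FA coverage are computed but kept out of the
default 7-feature classifier set.

# Classification

The 7-feature table is z-scored per column (sample sd, n-1) and fed to
a linear-kernel, maximum-margin SVM (soft-margin constraint C = 1 by
default; multi-class by one-vs-one majority vote), assessed with
stratified 5-fold cross-validation: per fold, train on the out-of-fold
rows, predict the in-fold rows; report the mean per-fold percent
correct and the pooled out-of-fold confusion matrix. Stratification
prevents empty-class folds at n ≈ 22 per class; a non-stratified mode
is available. Z-scoring is fitted on the full table before
cross-validation by default, mirroring a global preprocessing step; a
leakage-safe `scaling = "within_fold"` mode fits the scaler on each
training fold only, and is what the chance-level permutation check
uses.

Three tasks are standard: all four classes (`ABCD`), the three
well-separated classes (`ACD`), and the binary contrast of the woven
class against everything else (`ABCvD`). Feature importance for a
two-class contrast is ranked by the one-way ANOVA F ratio
(between-class over within-class mean square), ties broken by column
order; population heterogeneity is summarized by the coefficient of
variation (100 x sd / |mean|); group differences by one-way ANOVA with
Tukey HSD 95% intervals.

# The synthetic-scene generator

No public image corpus accompanies this workflow, so the package ships
a generator that renders calibrated scenes with full ground truth. Its
defaults *are* the study conditions of the test suite, chosen once to
be realistic for dermal fibroblasts at the four confinement states and
then left alone:

* field 256 x 256 px at 0.2 µm/px (a 51 µm field, one cell per scene);
* cell areas (µm²): A 400-750, B 250-900 (widest — B is the
  high-variance class), C 120-260 (smallest), D 350-700;
* shapes: A = ellipse (aspect 1.8-2.8); B = radial-Fourier "lamellar"
  blob whose per-cell ruffling amplitude is drawn from [0, max], so the
  class genuinely spans smooth ellipse-like through strongly lobed
  outlines; C = nearly round small blob; D = triangle with inward-bowed
  edges (concavity 0.25-0.45), so solidity falls distinctly below 1;
* nucleus: one ellipse of ~18% cell area at the cell centroid;
* FAs: per-class counts (A 18-32, B 8-36, C 5-10, D 8-16), log-normal
  areas (µm²; medians A 0.5, B 0.45, C 0.35, D 0.9 with sdlog 0.8-0.9,
  so all three triage bins receive mass), elongations (A 2.5-4 most
  elongated, D 1.1-1.7 least), and placements: body-wide (A, C),
  edge-biased band (B), or Gaussian perinuclear cluster with 2 µm scale
  (D). Footprints are kept non-overlapping so connected components
  remain countable;
* intensities: actin texture 0.55-0.80 inside the cell (sinusoidal
  fiber stripes), nucleus 0.85, FA puncta 0.75-0.95, cytosolic vinculin
  0.02 — deliberately at the noise floor. A *bright* uniform cytosol
  would make global Otsu split background-from-cell instead of
  FAs-from-everything (the FA pixel fraction, ~1%, can never dominate a
  three-level histogram), which contradicts how the workflow is meant
  to behave: with a dim, speckly cytosol the threshold lands below the
  FA level, and any noise speckle it admits is exactly what the 0.1 µm²
  cytosolic-background filter removes;
* noise: additive Gaussian (sd 0.02) everywhere, clipped to [0, 1]. No
  Poisson/PSF optics are simulated — the noise model only needs to
  exercise denoising and thresholding;
* z-stacks: `z_planes > 1` replicates the same 2D scene with per-plane
  Gaussian attenuation (peak at the central plane) and independent
  per-plane noise, enough to exercise maximum projection; true 3D
  geometry is out of scope.

Everything is driven by a single integer seed (child seeds derived
deterministically per scene), and identical seed + configuration yields
bit-identical output.

What passing tests on these scenes do and do not show: they validate
the *pipeline* — that segmentation recovers known ground truth, that
the metrics order the four archetypes as designed, and that the
classifier behaves sanely — not performance on real confocal data,
which has uneven illumination, out-of-focus light, touching cells and
staining artifacts that the generator does not emulate.

# Numerical choices and known limitations

* Otsu operates on a 256-level quantization; ties in the between-class
  variance are broken toward the lowest level. Constant images are an
  error (no threshold exists).
* Conditional erosion is applied once, synchronously (not iterated to
  stability); "surrounded by" is read as the full 8-neighbourhood.
* CLAHE tiling requires image dimensions divisible by the tile count;
  inputs are edge-replicated to the next multiple and cropped back.
* The FA dilation step (radius 1 px) inflates detected FA areas by
  roughly a one-pixel perimeter ring. At the default 0.2 µm/px this is
  a noticeable relative bias for small adhesions (and shifts most
  detected components above the nascent cutoff); it is identical across
  classes, so between-class orderings are unaffected. Work at finer
  pixel sizes if absolute FA areas matter.
* Archetype quantification is a package choice: only qualitative
  morphology is prescribed by the application, so the numeric ranges
  above were selected to realize the intended between-class orderings
  (C smallest area; D lowest solidity/rectangularity/G-function and
  highest E-slope; B widest variance) at the 22-cells-per-class scale,
  and are exposed in `class_archetype()` rather than hard-coded.
* Per-class sample sizes in the bundled study are 22 (88 cells total,
  the scale at which the three classification tasks are exercised);
  oracle suites use up to 200 points per configuration. These sizes are
  the package's validation choices.
* The archetype label-to-morphology mapping is fixed; if you need other
  morphologies, construct archetypes with different numeric ranges —
  the renderer honours any ranges that fit the field.

# A worked example

```{r example, eval = FALSE}
scenes <- generate_population(22, scene_config(), master_seed = 1)
res <- run_pipeline(scenes, k = 5, seed = 1)
aggregate(cbind(cell_area, solidity, g_function, e_slope) ~ class,
          res$features, mean)
sapply(res$reports, `[[`, "average_accuracy")
```

The same computation, plus univariate feature ranking and CV%
heterogeneity, is what `scripts/acceptance.R` performs end to end.
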