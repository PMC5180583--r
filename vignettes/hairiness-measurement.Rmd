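---
title: "Measuring pollinator hairiness as image entropy: methods and design"
author: "pilosity authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pollinator hairiness as image entropy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilosity)
```

## The measurement model

Hairiness is operationalized as the mean local Shannon entropy of the
image texture inside a marked body region. The reasoning: a bare, smooth
cuticle is locally near-uniform, so the gray-value histogram of a small
neighbourhood is concentrated and its entropy low; a hairy surface mixes
hair, cuticle, shadow and highlight within every neighbourhood, spreading
the histogram and raising its entropy. Entropy is computed per colour
channel from the 256-bin histogram of the 8-bit values within a
disk-shaped neighbourhood (the *radius of influence*),

$$H_{ij} = -\sum_v p_{ij}(v)\, \log_2 p_{ij}(v),$$

and the three channel layers are combined multiplicatively into the
combined entropy $E_S = E_R \cdot E_G \cdot E_B$ (unitless; the product
of three bit-valued entropies). The trait value for a region is the mean
of $E_S$ over its valid pixels, with the sample (n − 1) standard
deviation reported alongside.

Assumptions worth keeping in mind: the measure is *relative*. It depends
on the imaging scale (pixels per millimetre), focus quality, and
illumination, so values are comparable within a consistently photographed
specimen set, not across arbitrary imaging setups. Specular highlights on
shiny cuticle also raise local entropy; diffuse illumination at capture
time matters more than any parameter here.

## Parameters

* **Radius of influence `r`** (px, default 7; disk of 149 lattice
  offsets). The neighbourhood should span a few hair widths: at typical
  imaging scales hairs are 3.5–4.5 px wide, so r = 7 is about two hair
  widths. Larger radii smooth the entropy map and blur region borders;
  smaller radii starve the histogram (its entropy is bounded by
  $\log_2$ of the neighbourhood size, 7.22 bits at r = 7). The optimum
  shifts with the pixel-to-millimetre factor, which is why it is an
  exposed parameter rather than a constant.
* **`minArea`** (px², default 8): objects smaller than this are deleted
  as debris/noise during pre-processing.
* **`circTol`** (default 0.05): near-circularity tolerance. An object is
  deleted as pollen-like when $S = 4\pi A / P^2 \ge 1 - 0.05$. The bound
  is one-sided by geometry: the perimeter is the accumulated
  centre-to-centre distance along the traced boundary, and for a
  digitized disk this chord walk is *shorter* than the continuum
  circumference, so round blobs of radius 3–5 px land at
  $S \approx 1.05\text{–}1.35$ — at and above 1, never materially below.
  A two-sided band $|S - 1| \le 0.05$ would miss nearly all of them.
  Elongated structures (hairs, leg fragments) sit far below 1 and are
  kept either way.
* **`thresholdWindow`** (px, default 15) and **`thresholdSensitivity`**
  (default 1.45): a pixel is an artifact candidate when its value
  exceeds `sensitivity` × the mean over the in-region pixels of its
  window. Two design points here. First, the local mean is restricted to
  the marked region so that content outside it — typically the white
  card background — cannot raise the threshold just inside the region
  border and hide contaminants there. Second, the sensitivity default
  sits between the two object classes the stage must separate: pollen is
  among the brightest content in a specimen photograph (roughly 1.6–2×
  its local mean), while textured cuticle stays within ~1.3× of its own
  local mean. Values near 1 degenerate (on any roughly uniform surface
  every pixel exceeds a sub-unit multiple of its local mean), so the
  default must be comfortably above 1.
* **`polarity`** (`bright`/`dark`/`both`, default `bright`): whether
  artifacts are sought as locally bright objects (pollen on darker
  cuticle — the common case), locally dark, or both.
* **Pre-processing flag**: the whole artifact stage can be disabled,
  after which no pixel is excluded.

Excluded ("deleted") pixels are dropped from every histogram they would
enter, carry $E_S = 0$ with a validity flag of false, and are omitted
from region means and SDs.

## Model selection layer

Candidate models are all subsets of the region predictors (and body
length), optionally expanded with body-length × region interactions under
marginality (an interaction enters only when both main effects do). Each
is fitted by OLS with intercept; the Gaussian log-likelihood includes its
normalizing constants ($\ell = -\tfrac n2(\log(2\pi\,RSS/n) + 1)$, the
`logLik.lm` convention) and the AICc parameter count is k = coefficients
including the intercept, plus one for the residual variance. Ranking is
ascending in AICc with $\Delta_i$, Akaike weights and their cumulative
sum; ties break toward fewer terms, then lexicographic labels.

Numerical policies: candidates whose AICc would be undefined
(n − k − 1 ≤ 0) are screened out before fitting, with a reported count;
the model-size cap defaults to n − 4 terms. Rank-deficient designs are
dropped with a warning. A perfect fit (RSS = 0, only possible on
noiseless data) is kept in the table — ranked first, since its AICc is
−∞ — but excluded from the weight normalization, again with a warning.
Variance inflation factors are computed from the definition
$VIF_j = 1/(1 - R^2_j)$, with an infinite sentinel for exact
collinearity.

## What the synthetic generator emulates — and what it does not

`makeHairyPatch()` renders an amber mid-tone cuticle field carrying
darker, straight, anti-aliased hair strokes of width 3.5–4.5 px, with a
per-stroke brightness jitter (default ±25 gray levels, the lightness
variation real hair layers show with depth and inclination) and additive
Gaussian pixel noise (default SD 4). `hairDensity` is the target areal
coverage fraction (expected summed stroke area over patch area; strokes
may overlap), which keeps a ladder such as 0/0.2/0.5/0.8 meaningful from
bare to densely hairy. The per-stroke tone variation matters for the
measurement model: without it, neighbourhood histograms stop changing
once strokes overlap heavily and the entropy response flattens between
high coverages.

`addPollenArtifacts()` injects bright-yellow anti-aliased disks of radius
3–4.5 px (pollen of one plant species is size-uniform) at uniform
positions kept clear of the border and of each other, and returns the
exact circles as ground truth. `makeTraitTable()` draws region
predictors from a multivariate normal with exchangeable correlation
(default 0.3) and calibrates the residual SD so the population R² of the
true model equals a target (default 0.95).

What passing tests on these fixtures shows: the entropy statistic orders
surfaces by hair coverage, is repeatable across independent renderings of
one surface, and the artifact filter removes round bright contaminants
with few false deletions — under this geometry and palette. What they do
not show: robustness to focus stacking artifacts, specularity, curved or
criss-crossing hairs, colour-patterned cuticle, or pollen lying on
similarly bright surfaces; none of these are rendered. Real-data
behaviour must be validated on real photographs.

## Numerical and geometric conventions

* Coordinates: origin at the top-left corner, x = column, y = row,
  continuous pixel units; the centre of matrix cell [r, c] is
  (c − 0.5, r − 0.5).
* Rasterization: a pixel belongs to a region iff its centre is strictly
  inside the polygon under the even–odd rule; centres exactly on the
  boundary are outside. This makes rasterization deterministic and
  translation-equivariant, and an axis-aligned w × h rectangle covers
  exactly w·h pixels.
* Entropy borders: mirror (symmetric) padding, which avoids the
  artificial edge entropy a constant pad would inject. Per-region
  computation runs on the region's bounding box dilated by r, which is
  exactly equivalent to whole-image computation for in-region pixels.
* The structuring element is the exact Euclidean disk
  $\{(di, dj): di^2 + dj^2 \le r^2\}$ — 149 offsets at r = 7. (Legacy
  image-processing toolboxes approximate the disk with periodic lines
  and report 160 neighbours at the same nominal radius; exact and
  approximate disks give slightly different absolute values, one reason
  entropy values are comparable only within one software pipeline.)
* Histograms use identity binning of 8-bit values into 256 bins; inputs
  exceeding 255 are min–max rescaled to 8 bits with a warning.
* Connected components are 8-connected; the object boundary is traced
  with the Moore neighbourhood and the perimeter accumulates 1 per axis
  step and $\sqrt 2$ per diagonal step; a single-pixel object has
  perimeter 0 and undefined circularity (it is always handled by the
  area filter first).
* Up to four regions per image is treated as an advisory (a warning from
  `validateRoiSet()` and `saveRoiSet()`), not a limit; regions may
  overlap and are summarized independently.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
entropy oracle checks on 64 × 64 images, region measurements on
128 × 128 to 160 × 160 patches, and 200 replicate 10-species trait
tables (512 candidate models each). These sizes were chosen so the whole
suite completes in a couple of minutes on one CPU while leaving each
check statistically meaningful; measuring a full-resolution photograph
(tens of megapixels) with the same code is linear in pixel count times
neighbourhood size.

## Known limitations

* Entropy values are pipeline- and scale-relative (see above); compare
  only within a consistent imaging protocol and radius.
* The artifact filter removes *round, locally contrasting* objects; it
  will not remove pollen smears, overlapping pollen clumps (which merge
  into non-circular components), or grains optically similar to the
  surface under them.
* The degenerate-fit policy makes noiseless (simulated) responses safe,
  but weights are then conditional on the non-degenerate candidate set.
* With n around 10 species, AICc selection among 512 candidates recovers
  a strong true subset most of the time, not always (the acceptance
  script reports the measured rate, typically just under 80% at
  R² ≈ 0.95); single-dataset top models should be read together with
  Δi and the weight mass of the runners-up, as in the worked example.
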