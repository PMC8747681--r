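---
title: "Grain image phenotyping and seed storage trends: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grain image phenotyping and seed storage trends: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Seeds stored in genebanks slowly deteriorate even at −18 °C, and the
deterioration leaves traces in the seed coat: stored wheat grains become
redder and somewhat lighter, and redder coats germinate worse. `grainpheno`
implements a complete pipeline for detecting such storage trends from
ordinary photographs: grains of many genotypes and several harvest years are
scattered on a white background next to a color reference chart,
photographed, measured, and the per-seed descriptors are tested for a
monotone relationship with storage time and for association with
germination.

Because real multi-decade storage series are rare and rarely deposited, the
package ships a synthetic study generator with complete ground truth. Every
stage of the pipeline — segmentation, descriptor extraction, the trend
statistics — can therefore be validated by parameter recovery rather than by
eyeballing.

## Image processing model

Processing follows six stages per image:

1. **Chart measurement and scaling.** The chart layout (patch centers,
   reference sRGB values, physical patch pitch) is known; a dark corner
   fiducial confirms the chart is present. Patch colors are measured as the
   mean RGB of the central 50% of each patch, and the scale is
   `mm_per_px = pitch_mm / pitch_px`.
2. **Color correction.** A 3×4 affine transform is fitted by least squares
   from measured to reference patch colors and applied per pixel (rounded
   and clipped to [0, 255]). An affine map inverts any in-gamut linear
   illumination cast exactly; at least four linearly independent patches are
   required, and the residual RMS is reported. Patches that saturate (a
   channel at 255) bias the fit at the bright end, which is why the
   synthetic generator's default cast gains stay below the level that would
   clip the chart's white patch — mirroring how a photographer adjusts
   lighting.
3. **Segmentation.** Otsu's threshold on the BT.601 luminance of the
   corrected image, inverted (grains are darker than the white background),
   followed by a morphological opening (disk radius 2 px) and hole filling.
   The chart region is forced to background before thresholding and in the
   result.
4. **Contour extraction and filtering.** Connected components become
   candidate grains; components touching the border, outside the plausible
   area range (default 4–80 mm²) or too elongated (aspect > 5) are rejected
   with a logged reason.
5. **Size/shape descriptors** and 6. **color descriptors**, described below.

### Sub-pixel contours

Boundary polygons are traced by marching squares (`contourLines` at level
0.5) on a Gaussian-smoothed (σ = 1 px) copy of the binary mask. Contouring
the raw 0/1 raster yields a staircase polygon whose perimeter overestimates
a smooth boundary by ~6% for a disk, which would bias circularity to ~0.89
for a perfect circle; after smoothing, a rasterized disk of radius 100 px
measures circularity 0.990. Shape indices computed on analytic polygons are
exact, so tolerances are ±0.01 for polygons and ±0.02 for rasterized masks.
Contours are stored counter-clockwise with pixel centers at integer
coordinates (x right, y down).

## The 55 descriptors

Three size traits: length `sL` and width `sW` are the long and short side of
the minimum-area bounding rectangle (rotation invariant), area `sA` is the
filled pixel count, all scaled by `mm_per_px`. Four shape indices:

* circularity `sCi = 4π·area / perimeter²` — 1 for a circle, lowered by
  elongation and boundary roughness;
* roundness `sRo = 4·area / (π·major_axis²)` with the major axis taken as
  the maximum Feret diameter — insensitive to roughness; the isodiametric
  inequality keeps it ≤ 1;
* rugosity `sRu = Ps / Pc`, contour perimeter over convex-hull perimeter,
  ≥ 1 (the label `sRg` is accepted as a synonym in the literature);
* solidity `sSo = area / hull_area` ∈ (0, 1].

48 color traits come from four spaces under 8-bit conventions chosen so all
components span [0, 255] except hue (half-degrees, [0, 180]): HSV with
H = degrees/2; CIELAB via sRGB → D65 XYZ with L = 255·L*/100, a = a*+128,
b = b*+128; YCrCb per BT.601 full range. With these conventions a gray pixel
(g, g, g) maps to Y = g, Cr = Cb = 128, a = b = 128, and white maps to
L = 255. The BT.601 chroma gains overshoot 255 by up to 0.5 at the pure
primaries and are saturated, as in any 8-bit implementation.

Per space, two descriptor families:

* **Trimmed means** (`SPACE_mC`): for each component independently, the mean
  and *population* standard deviation are computed over all grain pixels;
  pixels deviating from the mean by strictly more than 3 SD are discarded
  (one iteration only; zero SD discards nothing), and the survivors' mean is
  reported. The population-SD convention is fixed by the worked example
  {100 × 10, 250 × 1}: mean 113.64, SD 43.12, the outlier deviates 136.4 >
  129.4 and is trimmed, giving exactly 100.
* **Dominant colors** (`SPACE_dCC_i`): k-means (k = 3) on the grain's pixels
  in that space, clusters ranked by descending pixel fraction (ties broken
  by the brightness component V/L/Y, or R+G+B for RGB), centroids reported
  as ranks 1–3. k-means uses `stats::kmeans` with 10 restarts and a per-grain
  seed derived by stable hashing of (image id, grain id), making the table
  reproducible. If a grain has fewer than 3 distinct colors the distinct
  colors fill the leading ranks and the rest duplicate rank 1 with fraction
  0, keeping the 48-column schema fixed. Trimming is per component and per
  space (whether joint trimming would be preferable is an open question; the
  per-component rule is the literal two-pass reading and is configurable in
  principle by replacing `trimmed_mean_3sd`).

## Trend statistics

Because harvest years are unevenly spaced, the calendar year is encoded
three ways: `Year01` (0 for the earlier half of the study years, 1 for the
later), `YearRank` (1..n chronologically) and `Year` (the year itself). On a
monotone effect the three give nearly identical correlations; `YearRank`
tends to be the most conservative and is the coding used for significance
testing. Genotype is a strong confounder, so each trait is centered by
genotype mean before correlating.

Significance uses an extreme-value decision rule with two randomization
experiments of 2000 replicates each:

* **permutation**: the year codes are shuffled and r recomputed;
* **null bootstrap**: x and y are resampled *independently* with
  replacement — breaking the pairing — and r recomputed.

Each experiment contributes a [min, max] envelope of replicate correlations;
the observed r is significant only if it falls strictly outside *both*
envelopes on the same side. Both experiments sample the no-association
distribution of r (the independent resampling in the bootstrap is essential:
resampling pairs would center the bootstrap envelope on the observed r
itself and no real trend could ever be declared significant). Under the
null, the observed correlation is exchangeable with the permutation
replicates, so the rule's two-sided type-I error is at most
2/(n_rep + 1) ≈ 10⁻³; the acceptance suite verifies ≤ 2·10⁻³ empirically
over 5000 null studies.

### Germination

Germination percentages (replicated tests per genotype-year) are analyzed
in five steps: one-way ANOVAs on genotype and on year; subtraction of the
year mean (the year effect dominates germination variance); exclusion of
whole genotype-year cells whose year-centered mean falls outside [−15, 15]
(the interval is treated as closed, so boundary values are retained, and
exclusion operates at cell level — all replicates of an outlying cell are
dropped); joining the retained cells' per-seed traits, each seed carrying
its cell's mean germination; Pearson correlation plus the envelope rule for
every trait. The unit of analysis is the seed, matching a per-seed trait
table; `year_trend_analysis` also offers genotype-year mean aggregation
since the original description does not fix the unit.

## Multivariate views

Traits and genotypes are both clustered by UPGMA (average linkage) on
Euclidean distances between standardized rows (traits are clustered as
items via distances between standardized trait columns across seeds — the
item/variable orientation is not fixed by convention, so both are exposed).
Merge heights are reported as ultrametric node heights (two items at
distance d merge at height d/2), so leaf-to-leaf path lengths reproduce the
cophenetic distances exactly; trees are exported as Newick. LDA (canonical
variates) is computed directly as the eigen-decomposition of W⁻¹B on
standardized traits, with axes scaled to unit pooled within-class variance;
a ridge proportional to mean(diag(W)) is added only when W is
computationally singular (and flagged). Class labels default to the k = 3
UPGMA clusters of genotype means, and biplots are produced separately for
color and size/shape trait sets. The implementation is cross-checked
against `MASS::lda` in the test suite.

## What the generator emulates — and what it does not

The generator draws genotype baselines (size, width ratio, coat color in
the 8-bit Lab convention), year effects and per-seed noise, renders grains
as ellipses with low-frequency sinusoidal boundary perturbation and radial
shading (the 3D-shape illumination gradient that motivates separating
brightness from tone), scatters them by rejection sampling so masks never
touch each other or the chart, applies a per-image diagonal color cast to
grains and chart alike, and quantizes to 8-bit PNG. Defaults follow the
emulated study design: 44 genotypes × 4 years (2003/2004/2009/2014), 17–20
grains per image, grain length ≈ 6.5 mm at 0.1 mm/px.

The year trend is parameterized by its population correlation: with
per-seed redness `a = a_g + β(rank − mean rank) + ε`, the slope β is solved
from the target genotype-centered correlation r and the noise SD via
`r² = β²s² / (β²s² + σ²)`. Defaults: r = −0.6 for redness (σ = 1.8 Lab
units) and r = −0.2 for lightness (σ = 4), signs chosen so that longer
storage (earlier year) means redder and lighter coats; hue trends emerge
with the opposite sign automatically because wheat-tan hue rises as redness
falls. The year effect on *size* is random (SD 0.25 mm), not monotone —
note that with only four year levels a random draw can still carry an
incidental monotone component, so a strong size "trend" in one synthetic
study is a property of that draw, not a bug.

Germination is linked to the *generator's* redness scalar (not to any
extracted descriptor, keeping ground truth independent of the pipeline
under test): cell mean = year mean + slope·(cell redness − year mean
redness), defaults 92.0/98.6/64.9/88.2% across the four years with slope
−1.5%/Lab-unit, replicate noise SD 3, plus planted outlier cells (five
strongly depressed and three elevated in the third year, two depressed in
the last) that exercise the exclusion rule.

Not emulated: awns, crease and embryo spot; touching grains (no watershed
is implemented); real ColorChecker spectral behavior or arbitrary chart
pose (the chart sits at a fixed, known location — for real photographs a
user-supplied layout/bounding box plays that role); shadows; non-linear
camera response. The magnitude of between-session illumination casts is not
documented for the emulated study, so the default gain range (0.92–1.04) is
an arbitrary but configurable choice kept inside the chart's gamut.
Passing recovery tests therefore demonstrate correctness of the algorithms
under a realistic but idealized forward model, not robustness to every
artifact of real photography.

## Problem sizes and determinism

The test suite validates at reduced scale, chosen to exercise every code
path with comfortable statistical margins: a 16-genotype × 4-year demo
study with 8–10 grains per 640×460 image (≈570 seeds; the standard error
of a correlation near −0.6 is ≈0.03, well inside the ±0.1 recovery band),
and 5000 null studies of n = 176 for the type-I error of the decision rule.
The full default configuration (176 images, ≈3300 seeds) runs in a few
minutes and is exercised through the same code.

All randomness is derived from one master seed; per-image and per-grain
streams are obtained by stable string hashing, so regenerating a single
image or grain reproduces the study bundle bit for bit, and pipeline reruns
with the same seed produce identical CSV checksums.

## Known limitations

* The affine correction cannot recover information lost to sensor
  saturation; casts that clip chart patches leave a residual bias at the
  bright end (logged via the clipped-pixel fraction).
* Boundary-roughness measures (`sCi`, `sRu`) depend mildly on the contour
  smoothing bandwidth; σ = 1 px is calibrated for grain-sized blobs
  (≥ ~30 px across) and the ±0.02 rasterization tolerance.
* The envelope rule controls the family-wise error per trait, not across
  the 55 traits; no multiple-testing correction is applied by design.
* `Year01` generalizes the original two-epoch split as "first half vs
  second half" of the study years; for the default four years it reproduces
  the 0/0/1/1 coding exactly.
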