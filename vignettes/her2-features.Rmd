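---
title: "Methods: biomarker-specific features for HER2 scoring"
author: "her2feat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker-specific features for HER2 scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2feat)
```

## Scope and model

`her2feat` scores IHC-stained breast-tissue image tiles for HER2 by
extracting four families of hand-crafted features that correspond to the
visual markers pathologists use — percentage and intensity of membrane
staining, staining texture, connectedness of stained regions, and overall
colour spread — and classifying the resulting 38-dimensional descriptor with
one-vs-all learners.

The package assumes 8-bit RGB tiles (any size from 3 px upward; 512 px tiles
are typical for whole-slide work) in which DAB staining is brown and the
counterstain bluish. All stain decisions are made in HSV space: a pixel is
*tissue* unless it is nearly white (see below), and *stained at threshold
`t`* iff it is tissue, its hue falls in a brown band, its saturation is at
least `t`, and it is not glare-bright. Because the threshold test is
inclusive, stain masks nest as `t` grows, which guarantees the
characteristic curve `p(t)` is non-increasing — a structural property the
test suite asserts over a thousand generated tiles rather than assumes.

## Parameters that matter

| key | default | meaning |
|---|---|---|
| `roi.bg_sat_max`, `roi.bg_val_min` | 0.08, 0.90 | background = S below / V above these fractions |
| `stain.hue_low_deg`, `stain.hue_high_deg` | 10, 50 | DAB brown hue band, degrees (may wrap 0) |
| `stain.val_max` | 0.98 | V ceiling for stained pixels (glare exclusion) |
| `tiles.min_roi_frac` | 0.40 | minimum tissue fraction for a tile to be used |
| `grid.*` | 0.10–0.50 step 0.02 | the 21-point saturation-threshold grid |
| `curve.n_points` | 10 | characteristic-curve downsampling size |
| `ulbp.substrate` | `"mask"` | LBP codes on the binary mask or on masked saturation |
| `ulbp.similarity_threshold` | 0.95 | mean Pearson r above which curve pairs are redundant |
| `conn.t0`, `conn.connectivity` | 0.10, 8 | binarisation threshold and adjacency for connectedness |
| `learner.logreg_C` | 1.0 | inverse ridge strength (penalty `lambda = 1/(nC)`) |
| `learner.svm_*` | RBF, cost 1, median-heuristic gamma | SVM settings |

The slide background definition deserves a note: tile-level pipelines rarely
publish one, so `her2feat` defines background as *bright and unsaturated*
(near-white glass), making both counterstained and stained tissue — chromatic
or dark — part of the ROI. The DAB band [10°, 50°] covers the orange/brown
sector; both are configurable because staining protocols vary.

## Design choices where the design was open

**LBP substrate.** The uniform-LBP components are computed on the binary
stain mask at each threshold, over interior ROI pixels, with the standard
`>=` tie convention (ties count as a set bit) and the radius-1 ring of the 8
axis/diagonal neighbours, without interpolation. On a binary substrate this
has two consequences worth stating plainly: any *unstained* centre ties with
all its neighbours and lands in `U8`, and as the threshold passes the most
saturated stained pixel every pattern becomes constant, driving `U0..U7` to
zero. `U8` therefore acts as a background/constant-region sink, which is
exactly why it is excluded from the feature set. An alternative substrate
(`ulbp.substrate = "saturation"`) computes codes on the saturation channel
zeroed outside the mask, for users who prefer a greyscale texture source;
the mask substrate is the default because its limit behaviour is clean and
exactly testable.

**Curve downsampling.** For the 10-of-21 reduction the package keeps every
second grid point starting at `t = 0.10` (values `v0, v2, ..., v18`),
privileging the low thresholds where staining percentages are largest and
most class-informative. For sizes where the step-2 rule does not apply
(including the degenerate `n = 2`) it falls back to evenly spaced indices
`round(k(m-1)/(n-1))`, which keeps both endpoints. The ULBP curves use the
evenly spaced rule at five points (grid indices 0, 5, 10, 15, 20): those
curves are nearly linear, so endpoint-preserving uniform sampling loses
little.

**Curve merging.** Redundancy among the eight ULBP curves is measured as the
per-sample Pearson correlation between curves, averaged over samples, with
degenerate (constant-curve) samples skipped per pair and an all-degenerate
pair reported as undefined rather than zero. The reduced descriptor follows
a fixed `U0..U4` selection; on a given dataset the discovered redundant
pairs may differ from those that motivated it, which is why
`pairwise_curve_similarity()` is exposed as a diagnostic.

**Connectivity.** The connectedness measure uses 8-adjacency by default:
membrane staining forms thin, often diagonal strands that 4-adjacency would
fragment. The denominator is the ROI pixel count, not the tile area, so the
measure is comparable across tiles with different tissue coverage.

**b\* mapping.** The b\* channel is shifted by +128 and clamped to [0, 255]
to form integer histogram bins; the sRGB-attainable b\* range fits inside
this window. The histogram is taken over the whole tile (background
included), and entropy is reported in bits — any other log base would only
rescale it.

**Classifiers.** One binary classifier per class on z-scored features
(standardisation learned inside each training fold — percentage-valued and
fraction-valued features differ by two orders of magnitude, and leakage-free
scaling is the only defensible default). Logistic regression is
ridge-penalised (`glmnet`, penalty `1/(nC)`, `C = 1`), which keeps the fit
defined on separable data. The SVM is kernelised (RBF) by default with the
median heuristic for the kernel width; whether a linear machine would serve
equally well is dataset-dependent, so the kernel is a config option.
Prediction is the argmax of decision scores, ties broken toward the lower
class (ties are reported via a message).

## The synthetic generator

`generate_tile()` emulates the three properties the features are designed to
read: *how much* tissue stains, *how saturated* the stain is, and *how
spatially coherent* it is. A smooth random field (uniform noise low-pass
filtered at the class's correlation length, built by circular FFT
convolution so the field is stationary) is thresholded at the exact quantile
that stains the target tissue fraction; stained pixels get brown hues and
class-dependent saturation, remaining tissue a bluish counterstain, and a
background fraction is painted near-white. Defaults per class: stained
fraction 0.05 / 0.15 / 0.30 / 0.55, mean saturation 0.20 / 0.30 / 0.50 /
0.75, correlation length 4 / 8 / 12 / 16 px for scores 0 / 1+ / 2+ / 3+ —
monotone separations that reproduce the clinical curve-shape rules (score-0
curves below the 10% line, 3+ curves above the 30% line, 1+ dropping below
10% within the grid, 2+ spanning a wide intermediate range). Stained-pixel
saturation is clipped to [0.13, 1] so every stained pixel stays above the
lowest grid threshold; the achieved stain fraction at `t = 0.10` then pins
to the target up to 8-bit quantization, and the ground-truth record reports
fractions measured on the final quantized tile, not the drawn values.

What the generator does **not** emulate: nuclei, cell outlines and membrane
micro-morphology, stain deconvolution physics, scanner noise, tissue folds,
or ambiguous mixed-pattern tiles. Passing tests on synthetic data therefore
demonstrate that the pipeline measures what it claims to measure under
controlled conditions — not that clinical accuracy figures transfer to real
slides, where class overlap is far larger.

## Numerical and degenerate-input conventions

* Empty-ROI tiles raise an explicit "no tissue in tile" error carrying the
  tile id; they are normally removed upstream by the 40% ROI filter
  (boundary inclusive).
* An empty LBP evaluation set returns an all-zero histogram flagged `empty`,
  never a 0/0.
* Curve areas use the trapezoidal rule on the raw grid; no interpolation or
  polynomial fitting (smooth-curve fits were deliberately left out of the
  feature set, which stores sampled points instead of coefficients).
* Histogram normalisation and ULBP normalisation are exact up to 1e-9 and
  tested as invariants.
* All randomness — tile generation, splits, fold shuffles — derives from one
  documented integer seed per entry point; per-tile and per-repeat seeds are
  derived arithmetically and stay below 2^31.
* Hue bands may wrap through 0°; membership is tested modulo 360.

## Problem sizes used in the checks

The default study conditions are 200 tiles per class at 128 px, master
seed 1, for the cross-validation and class-separation checks; curve
monotonicity is exercised on 1,000 generated 64 px tiles, the LBP and
connected-component oracles on 100 random 16 px and 32 px masks, and the
ground-truth pinning invariant at 256 px. Tile size mainly sets the pixel
count behind each feature; the class geometry is scale-free, so 128 px tiles
carry the same structure as 512 px ones at a sixteenth of the work.

## Known limitations

* The ROI definition is tissue-vs-background only; no membrane-specific
  filtering is applied before feature computation.
* The LBP ring is the integer radius-1 neighbourhood; multi-radius or
  interpolated circular variants are out of scope.
* Whole-slide reading (NDPI pyramids) and slide-level score aggregation are
  out of scope: the package consumes pre-extracted tiles and scores tiles.
* Classifier hyperparameters are sensible defaults, not tuned values; the
  learners exist to evaluate the features, which is the package's focus.
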