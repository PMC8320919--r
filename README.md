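# her2feat

Biomarker-specific image features for automated HER2 scoring of
immunohistochemistry (IHC) stained histology tiles.

## The problem

HER2 (human epidermal growth factor receptor 2) status in breast cancer is
assessed on IHC-stained slides, where the DAB chromogen marks HER2-positive
cell membranes brown against a blue haematoxylin counterstain. Pathologists
assign one of four scores — 0, 1+ (negative), 2+ (equivocal), 3+ (positive) —
from the intensity, percentage and pattern of membrane staining. `her2feat`
computes, from RGB image tiles cut out of whole-slide images, a compact set of
hand-crafted features that map directly onto those visual criteria, and
evaluates them with one-vs-all classifiers. It is aimed at digital-pathology
researchers who want interpretable, biomarker-aligned descriptors rather than
end-to-end learned representations.

## The feature model

For a tile with tissue region (ROI) `R` and DAB stain mask
`M(t) = {p in R : hue(p) in brown band, S(p) >= t}` at saturation threshold
`t`, the package computes four feature families, 38 values in total:

1. **Characteristic curve** (10 values) — the percentage of stained tissue
   `p(t) = 100 |M(t)| / |R|` sampled at 21 thresholds `t = 0.10, 0.12, ..., 0.50`.
   Mask nesting makes `p(t)` non-increasing; the curve is smooth, so it is
   downsampled to every second grid point starting at `t = 0.10`.
2. **Rotation-invariant uniform LBP curves** (25 values) — at each threshold
   the 8-bit local binary pattern of every interior ROI pixel of the stain
   mask is binned by its number of set bits into components `U0..U8`
   (patterns with more than two circular 0-1 transitions are set aside;
   `U8`, the constant-background bin, is discarded). The per-threshold
   components form 8 feature curves; similarity analysis collapses them to
   `U0..U4`, each sampled at 5 thresholds.
3. **Connectedness** (1 value) — the largest 8-connected component of
   `M(0.10)` as a percentage of `|R|`: strong complete membrane staining
   coalesces into one dominant component.
4. **b\* histogram statistics** (2 values) — entropy `-sum p_i log2 p_i` and
   energy `sum p_i^2` of the 256-bin histogram of the CIE-Lab b\* (blue-yellow)
   channel, which carries the counterstain-vs-DAB contrast.

Feature tables feed a one-vs-all classifier (ridge logistic regression or an
RBF SVM) with per-fold z-scoring, evaluated by stratified holdout or repeated
stratified k-fold cross-validation.

A synthetic tile generator produces membrane-like staining whose stained
fraction, saturation and spatial coherence vary by class, so the whole
pipeline is testable without clinical data.

## Worked example

```r
library(her2feat)

dat   <- generate_dataset(n_per_class = 25, seed = 1)   # 100 synthetic tiles
feats <- extract_dataset(dat$tiles, dat$labels)
feats[c(1, 30, 60, 90), c("tile_id", "label", "cc_00", "conn", "entropy", "energy")]
#>       tile_id label  cc_00   conn entropy energy
#>   tile_0_0001     0  4.998  0.705   4.555  0.057
#>  tile_1p_0005    1+ 15.001  5.629   4.922  0.047
#>  tile_2p_0010    2+ 30.001 12.003   5.380  0.034
#>  tile_3p_0015    3+ 54.998 24.651   5.734  0.023

repeated_cv(feats, learner = "logreg", folds = 5, repeats = 5, seed = 1)
#> accuracy = 100.00%
#> over 5 trials: mean 100.00%, sd 0.00%
#> confusion matrix (rows = actual, columns = predicted):
#>       predicted
#> actual   0  1+  2+  3+
#>     0  125   0   0   0
#>     1+   0 125   0   0
#>     2+   0   0 125   0
#>     3+   0   0   0 125
```

`cc_00` is the percentage of tissue stained at the lowest threshold: ~5% for
score 0 (below the 10% line), ~55% for 3+ (above the 30% line). Connectedness
and entropy rise with score while energy falls, mirroring how a pathologist
reads staining percentage, completeness and spread. The confusion matrix
pools the held-out predictions of all five CV repeats; synthetic classes are
deliberately well separated, so accuracy is at ceiling here.

A command-line wrapper is installed with the package
(`system.file("cli", "her2feat", package = "her2feat")`) exposing
`synth`, `extract`, `train` and `sweep` subcommands over the same functions.

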