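---
title: "Methods: plot-level cotton boll counting from aerial RGB imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plot-level cotton boll counting from aerial RGB imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bollcount)
```

## The problem and the model

In cotton breeding trials, yield is evaluated per plot — a short row
segment of one genotype. After defoliation the open bolls are the bright,
near-neutral objects in a downward aerial RGB image, and counting them is
a usable proxy for plot yield. `bollcount` implements that counting
pipeline in four stages:

1. **Background removal by color indices.** Two per-pixel indices shrink
   the problem before any learning happens. Vegetation is flagged by a
   modified excess-green-minus-excess-red index on chromatic coordinates
   ($R_{norm} = R/(R+G+B)$, etc.):
   $$ExGR_{mod} = 2.5\,G_{norm} - 3\,R_{norm} - B_{norm},$$
   which is invariant to uniform intensity scaling and lies in
   $[-3, 2.5]$ (pure green scores 2.5, any gray $-0.5$, pure red $-3$).
   Soil is flagged by a CIELAB-based index
   $$Soil_{Idx} = 0.5\,L_{norm} - 2\,a_{norm} + b_{norm},$$
   which doubly penalizes the positive $a^*$ of tan/brown soil while
   rewarding lightness; reference white scores 0.5.
2. **SVM pixel classification.** Every retained pixel is described by
   eleven features — its $(row, col)$ location and the nine color
   components R, G, B, H, S, V, $L^*$, $a^*$, $b^*$. Recursive feature
   elimination with a random-forest importance estimator reduces the nine
   color channels (coordinates are never candidates) to the four most
   informative; an RBF-kernel SVM ($C = 1$, bandwidth $\gamma =
   1/(d\,\mathrm{Var}(X))$, the "scale" convention) is trained on a 4:1
   train/test split of pixels from a *single* annotated plot, and
   evaluated by accuracy, precision, recall, F1 and the Type I/II error
   rates.
3. **Morphology and counting.** The predicted cotton mask is eroded with
   a $3\times3$ elliptic structuring element (the discrete ellipse at
   that size is the 5-pixel cross), removing isolated false positives,
   then dilated with a $5\times5$ rectangular element, consolidating each
   boll into one solid cluster. Maximal 8-connected (Moore-neighborhood)
   components are the bolls; the component count is the plot's estimate.
4. **Evaluation and genotype statistics.** Predicted counts are regressed
   on ground truth (OLS), reporting $R^2$, the RMSE normalized by the
   observed truth range (NRMSE), the mean absolute percentage error
   (MAPE), and residual outliers beyond 3 standard deviations. Genotypes
   are compared by per-genotype mean and standard error, one-way ANOVA at
   $\alpha = 0.05$, and Fisher's LSD letter groups computed from the
   pooled error mean square.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `veg_threshold` | 0 | pixels with $ExGR_{mod}$ above it are removed as vegetation; 0 is the classic ExG$-$ExR crossing |
| `soil_threshold` | 0.25 | surviving pixels with $Soil_{Idx}$ below it are removed as soil |
| `C`, `gamma` | 1.0, `"scale"` | SVM cost and RBF bandwidth convention |
| `selected_k` | 4 | color features kept by RFE |
| `split_ratio` | 4:1 | train:test pixel split, train $= \lfloor 0.8N \rfloor$ |
| `se_erode`, `se_dilate` | 3×3 elliptic, 5×5 rect | morphological elements |
| `min_area` | 1 | optional minimum cluster area (off by default) |
| `alpha` | 0.05 | significance level for ANOVA / LSD |

Design choices where the method itself leaves room:

* **Index normalizations.** $ExGR_{mod}$ uses chromatic coordinates;
  per-channel max pre-scaling cancels for 8-bit data. For $Soil_{Idx}$
  the normalized components are taken as $L^*/100$, $a^*/127$, $b^*/127$
  — division by the conventional component maxima, keeping all terms
  comparable and unitless. A per-image min–max scaling would change the
  index values; the fixed convention was chosen for portability across
  images and is applied everywhere, including the 0.5 white anchor.
* **Removal directions and thresholds.** Vegetation is removed *above*
  the greenness threshold and soil *below* the soil-index threshold.
  `soil_threshold = 0.25` was fixed once from the palette geometry of the
  synthetic scenes: soil samples span roughly 0.11–0.48 on the index
  while boll pixels — including the darkest rims at $L^* \approx 60$ —
  stay at or above $\approx 0.25$. Both thresholds and directions are
  config-exposed; the soil stage is deliberately permissive, since the
  classifier downstream handles residual soil well, whereas boll pixels
  lost here are unrecoverable.
* **Degenerate pixels.** $(0,0,0)$ pixels (zero fill from polygon
  clipping) take index value 0 and are always removed, so clipping
  artifacts can never enter training or prediction.
* **No feature standardization.** The SVM sees raw feature scales; the
  "scale" bandwidth absorbs overall variance. Adding a standardizer
  would silently change the model class, so none is applied.
* **Split and estimator details.** The pixel split is an unstratified
  uniform shuffle under a user seed. The RFE estimator is a 100-tree
  random forest with impurity (Gini) importance, seeded; these are
  config-exposed since the method itself does not pin them.
* **Metric edge cases.** Any metric with a zero denominator (no
  predicted positives, no actual positives, constant ground truth for
  NRMSE, a zero truth count for MAPE) is reported as `NA` rather than
  raising, so batch evaluation survives degenerate plots. Identities
  that must hold exactly — precision + Type I $= 100$, recall + Type II
  $= 100$, $F1 = 2TP/(2TP+FP+FN)$, NRMSE $\times$ range $=$ RMSE — are
  enforced by tests at $10^{-9}$–$10^{-12}$.
* **Morphology border convention.** Outside-image positions count as
  background for erosion (border foreground erodes) and are ignored for
  dilation. The erosion-then-dilation pair never creates foreground
  outside the dilation neighborhood of the input, and on disjoint convex
  clusters a larger erosion element can only reduce the count. On
  arbitrary dense masks erosion *can* split a cluster and raise the
  count; that regime does not occur for well-separated bolls.
* **LSD letters.** Groups are sorted by descending mean; maximal runs of
  mutually non-different groups (pairwise LSD with unequal-$n$ standard
  errors) each get one letter. No pair sharing a letter is significantly
  different — the property the tests enforce. Genotypes observed on a
  single plot carry an undefined SE and no letter.
* **Outlier handling.** Residual outliers (3-SD rule) are flagged but
  kept in the reported fit; `refit_without_outliers = TRUE` reports the
  fit with them removed while keeping the flags. A numerically perfect
  fit leaves only floating-point noise in the residuals, which is never
  flagged.

## The synthetic scene generator

Field imagery for this problem is rarely shareable, so the package ships
a generator whose scenes exercise every stage with known truth. A scene
is composed of the four pixel classes of a defoliated cotton plot:

* **soil** — a small per-scene palette (8 colors) drawn in CIELAB
  ($L^*$ 45–65, $a^*$ 5–15, $b^*$ 15–30), assigned per pixel;
* **vegetation** — random ellipses in high-green RGB, covering a target
  fraction (default 0.25) of the scene;
* **wood** — thin light-brown segments ($L^*$ 62–75), the classic
  false-positive confuser: bright enough to resemble cotton in lightness
  while differing in chroma;
* **cotton** — disks of radius 2–5 px with near-neutral color
  ($|a^*|, b^*$ small), center lightness 85–98 falling off linearly by
  25 $L^*$ units toward the rim, emulating shaded boll edges — the
  false-negative mechanism.

Boll centers are rejection-sampled with a minimum separation (default
15 px) and a 10,000-rejection cap that raises an explicit placement
error. A left-to-right illumination gradient (default $\pm5\%$) and
additive Gaussian noise (sd 3 intensity units) are applied last;
everything is reproducible bit-for-bit from the seed. Scene size
defaults to 240×360 px — large enough for ~200 separated bolls, small
enough that the full train-plus-20-plot evaluation runs in about a
minute on one CPU; those are the problem sizes the test suite and the
acceptance script use.

What the generator does *not* emulate: photorealistic texture, occlusion
and 3D canopy structure, stitching seams, radiometric drift between
images, and bolls that overlap in the 2D projection. Consequently the
synthetic classifier separates classes essentially perfectly, and
passing the end-to-end recovery check ($R^2 \ge 0.9$, MAPE $\le 15\%$
over 20 scenes of 20–200 bolls) demonstrates that the pipeline's
mechanics — indices, feature selection, SVM, morphology, counting,
statistics — compose correctly, not that field accuracy would match.
On real imagery the classifier faces shadows, mixed pixels and
reflective branches, and accuracy is necessarily lower. The generator
*does* reproduce the two qualitative failure modes worth testing:
crowding bolls below the dilation merge distance depresses the count
(under-counting in dense plots), and dark boll rims are the pixels lost
first when thresholds tighten.

## Worked example

```{r example, eval = FALSE}
library(bollcount)

scene <- generate_scene(scene_config(n_bolls = 60, seed = 42))
fit <- train_pipeline(scene$image, scene$mask)
fit$metrics

res <- estimate_plot_yield(generate_scene(scene_config(n_bolls = 120,
                                                       seed = 43))$image, fit)
res$boll_count
autoplot(res)
```

## Known limitations

* Counting equals connected-component counting: two bolls closer than
  the dilation merge distance are one cluster. No area-based
  disaggregation is attempted; dense plots under-count.
* GeoTIFF geo-keys are not parsed; georeferencing travels in a JSON
  sidecar (`<image>.aux.json`) or is supplied explicitly. Clipping is
  axis-aligned bounding box with zero fill — no rotation or resampling.
* The classifier is trained from a single annotated plot by design;
  transfer across illumination conditions requires retraining.
* MAPE is undefined when any ground-truth count is zero; NRMSE when the
  truth range is zero. Both surface as `NA`.
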