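# bollcount

Plot-level cotton yield estimation from aerial RGB imagery.

In cotton breeding trials, the number of open bolls visible in a
downward aerial image of a defoliated plot is a fast, non-destructive
proxy for plot yield. `bollcount` implements the full counting pipeline
for breeders and phenotyping engineers:

1. **Color-index background removal** — vegetation pixels are dropped
   where the modified excess-green-minus-excess-red index
   `ExGR_mod = 2.5·G_norm − 3·R_norm − B_norm` (chromatic coordinates,
   range [−3, 2.5]) exceeds a threshold; soil pixels where the
   CIELAB-based index `Soil_Idx = 0.5·L_norm − 2·a_norm + b_norm`
   falls below one.
2. **SVM pixel classification** — each retained pixel carries eleven
   features (row, col, R, G, B, H, S, V, L\*, a\*, b\*); recursive
   feature elimination with a random-forest estimator keeps the 4 most
   informative color channels, and an RBF-kernel SVM (C = 1,
   γ = "scale") trained on one annotated plot labels pixels cotton /
   non-cotton. Held-out accuracy, precision, recall, F1 and Type I/II
   error rates are reported.
3. **Morphology + connected components** — a 3×3 elliptic erosion (the
   5-pixel cross) removes speckle, a 5×5 rectangular dilation
   consolidates each boll, and maximal 8-connected components are
   counted: the component count is the plot's boll estimate.
4. **Evaluation & genotype statistics** — predicted counts are regressed
   on ground truth (R², NRMSE over the truth range, MAPE, 3-SD residual
   outliers), and genotypes compared by mean ± SE, one-way ANOVA and
   Fisher's LSD letter groups.

A synthetic scene generator with exact per-pixel truth (soil, vegetation,
woody debris, bolls with radial lightness falloff) makes the whole
pipeline testable without field imagery.

## Worked example

```r
library(bollcount)

scene <- generate_scene(scene_config(n_bolls = 60, seed = 42))
tidy(background_mask(scene$image))
#> # A tibble: 3 × 3
#>   stage            pixels pct_of_raw
#>   <chr>             <int>      <dbl>
#> 1 raw               86400      100
#> 2 after_vegetation  66368       76.8
#> 3 after_soil        53121       61.5

fit <- train_pipeline(scene$image, scene$mask)
fit$selected_features
#> [1] "S" "b" "B" "a"
fit$metrics
#> Pixels: 10625 (TP 512, TN 10113, FP 0, FN 0)
#> accuracy 100.0% | precision 100.0% | recall 100.0% | F1 100.0%
#> Type I 0.0% | Type II 0.0%

res <- estimate_plot_yield(
  generate_scene(scene_config(n_bolls = 120, seed = 43))$image, fit)
res
#> <boll_count_result> 120 boll(s), 9606 foreground px on 240 x 360
```

The background stages keep 61.5% of this scene (synthetic soil is
deliberately only partially removed — the classifier handles the rest);
feature selection lands on saturation and chroma channels, which
separate near-neutral bright bolls from green vegetation and brown
wood; and the 120 rendered bolls are recovered exactly because the
scene keeps them above the morphological merge distance. See the
methods vignette (`vignettes/boll-counting-methods.Rmd`) for what
synthetic performance does and does not imply about field imagery.

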