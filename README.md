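# sijmri

Automated delineation and lesion grading of the sacroiliac joints (SIJs)
on coronal MRI, for imaging scientists working on axial spondyloarthritis
(axSpA).

The package implements a two-stage pipeline:

1. **Open-contour delineation by unit vector fields.** Each SIJ is an open
   polyline, not a closed region, so segmentation masks fit it poorly.
   A compact encoder–decoder regresses, per joint, a per-pixel *unit
   vector field* v̂(x) — pointing at the nearest contour vertex away from
   the contour, and along the contour within a narrow band — together with
   two Gaussian endpoint heatmaps ("source" and "sink", maximum 1,
   variance tied to the inter-contour sacrum area). The contour is
   extracted by walking from the source peak along the field in unit
   steps until the sink peak is reached. Accuracy is measured as the
   closest-point RMS between predicted and annotated vertices, summarised
   as empirical quantiles per proportion of the test set; a 21-heatmap
   landmark-regression baseline is included for comparison.
2. **Multi-reader lesion classification.** Rotation-aligned,
   slice-consistent minimum bounding boxes around each delineated joint
   are cut from the registered T1-weighted and STIR volumes; a shared
   encoder embeds both crops, and 14 linear heads per joint score five
   binary lesions (bone marrow oedema, fatty lesions, erosions per
   quadrant; sclerosis, ankylosis per joint). Training embraces label
   disagreement: every reader, read session, and consensus level is a
   rank-1 annotator matrix A = a ⊗ b applied as (I + A)p and arranged in
   a consensus tree (root = inter-reader consensus, then per-reader
   consensus, then sessions), with loss CE + λ·Σᵢ tr(Aᵢ). At inference
   the root-node prediction is compared against inter-consensus labels
   with AUC, balanced accuracy, sensitivity and specificity, under
   per-patient cross-validation.

No clinical data ships with the package. A synthetic module generates
contour-annotated slices and volumes, paired-contrast crops with planted
lesion effects, and multi-reader labels with known flip rates, so the
whole pipeline is testable end to end; see the methods vignette
(`vignettes/sijmri-methods.Rmd`) for the models, defaults and their
rationale.

## A worked example

Generate a synthetic volume, delineate it with an analytically built
field (no training needed for the geometry), and score the recovery:

```r
library(sijmri)

set.seed(1)
slice <- make_slice(scene_spec(size = 64, absence_prob = 0))

# analytic targets for the left joint, then walk source -> sink
field <- build_target_uvf(slice$left, c(64, 64))
sigma <- heatmap_sigma(slice$left, slice$right)
ends  <- build_endpoint_heatmaps(slice$left, c(64, 64), sigma)
walked <- walk_contour(field, ends$source, ends$sink, walk_params(), "left")

closest_point_rms(walked, slice$left)
#> [1] 0.1546468
```

A walked contour tracks the annotation to a fraction of a pixel. The
trained path does the same from images alone:

```r
train <- lapply(1:200, function(i) make_slice(scene_spec()))
model <- train_delineator(train, desk_delineator_config(),
                          augment = NULL, steps = 300, batch_size = 8)
res <- delineate_volume(model, make_slice(scene_spec(), seed = 99)$image,
                        walk = walk_cascade())
res
#> # A tibble: 2 x 4
#>   slice side  present contour
#>   <int> <chr> <lgl>   <list>
#> 1     1 left  TRUE    <sij_plyl>
#> 2     1 right TRUE    <sij_plyl>
```

On 40 held-out synthetic slices this recipe reaches a mean closest-point
RMS below 2 px (about 1.5-1.9 px depending on the seed) while the
21-heatmap baseline sits above 3 px at the same training budget
(`experiment_delineation(seed = 1)`).

For the multi-reader machinery:

```r
ex <- experiment_reader_noise(n = 2000, rates = c(0.1, 0.25), seed = 2)
ex$nodes
#> # A tibble: 6 x 5
#>   node  disagreement reader true_rate abs_error
#>   <chr>        <dbl>  <int>     <dbl>     <dbl>
#> 1 R1S1         0.112      1      0.1    0.0115
#> 2 R1S2         0.106      1      0.1    0.00603
#> 3 R1S3         0.107      1      0.1    0.00723
#> 4 R2S1         0.239      2      0.25   0.0105
#> 5 R2S2         0.239      2      0.25   0.0106
#> 6 R2S3         0.240      2      0.25   0.0104
```

The fitted session nodes recover the simulated per-reader flip rates to
within about a hundredth, while the root prediction stays clean
(`ex$root_accuracy` = 0.9925).

## Command line

A thin launcher in `inst/cli/sijmri` exposes the pipeline as
subcommands — `simulate`, `train-delineator`, `delineate`, `extract-roi`,
`train-classifier`, `classify`, `evaluate`, `crossval` — all seeded and
writing outputs atomically. `sij_cli()` is the same entry point from R.

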