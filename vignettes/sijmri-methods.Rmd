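---
title: "Delineating and grading sacroiliac joints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating and grading sacroiliac joints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the models implemented in `sijmri`, the choices
behind their defaults, and what the synthetic test bed does and does not
establish. The package has two stages: open-contour delineation of the left
and right sacroiliac joints (SIJs) on coronal MRI slices, and multi-label
lesion classification of the extracted joint regions trained under a
hierarchical multi-reader label model.

## Stage 1: open-contour delineation by unit vector fields

Segmentation masks handle open anatomy poorly: the SIJ is the *space*
between sacrum and ilium, annotated as an open polyline of 2 to 21
vertices per slice. We therefore regress, per joint, a **unit vector
field** (UVF) over the slice together with two Gaussian endpoint heatmaps,
and extract the contour by walking the field from the source peak to the
sink peak.

### The target field

At a pixel away from the contour the target vector points at the nearest
annotated vertex. Within a band of `on_contour_radius` around the polyline
itself, the vector instead runs along the nearest segment, toward that
segment's later vertex, so a walker riding the contour is carried forward;
pixels near the final vertex reuse the final segment's direction. All
vectors are unit norm.

Two numerical choices matter here.

* **Band width.** The band must cover the rasterised contour: a segment
  crossing the pixel grid diagonally can pass ~0.71 px from the nearest
  pixel centre, so the geometric default is 0.75 px. Anything narrower
  leaves "gaps" where both adjacent pixels point *at* the contour from
  opposite sides; a unit-step walker then oscillates in a two-point orbit
  and never progresses. For *training targets* the band is widened further
  (2 px in the desk recipe): a compact regressor reproduces a thick smooth
  tangential channel far more reliably than a one-pixel ridge.
* **Endpoint scale.** Endpoint heatmaps are isotropic Gaussians with
  maximum 1 and a standard deviation tied to the anatomy:
  `sigma = frac * sqrt(area of the inter-contour ("sacrum") region)`, or
  `frac * contour length` when only one contour is present and no region
  exists. The proportionality constant is a free parameter; the pipeline
  default is `frac = 0.05`, and the desk training recipe uses `0.1` so
  that endpoint supervision is not vanishingly sparse on a 64 px grid.

### Walking

The walk starts at the integer argmax of the source heatmap and repeatedly
steps `step_length` (default 1) pixels along the bilinearly interpolated,
renormalised field, terminating when it comes within `stop_radius`
(default: the sink sigma, estimated from the heatmap mass when unknown) of
the sink argmax; the sink argmax is appended as the final vertex. A
presence threshold of 0.3 on the source peak declares a joint absent —
the network is trained on slices with out-of-frame joints precisely so
that their endpoint heatmaps stay flat.

Three integration details stabilise walking on *regressed* (as opposed to
analytic) fields:

* **Midpoint sampling.** The step direction is re-sampled half a step
  ahead (RK2). Steps keep unit length; the midpoint evaluation carries the
  walker across the discontinuous band edges.
* **Inertia and no-backtrack options.** Learnt fields carry sparse local
  defects — small attractors where the regression is locally wrong — that
  trap a memoryless walker in limit cycles. `walk_params(inertia = w)`
  blends the previous direction into the current one;
  `no_backtrack = TRUE` projects out direction reversals greater than 90°.
* **The cascade.** `walk_cascade()` tries a plain walk first and falls
  back to increasingly inertial retries only when a walk fails to
  converge, so robustness is bought only where it is needed and the
  accurate plain walk is kept everywhere else.
* **Endpoint candidates.** Regressed endpoint planes can collapse both
  peaks onto one end or swap source/sink identity. When no cascade stage
  converges, `walk_targets()` retries from a source argmax masked away
  from the sink (a contour's endpoints are distinct by definition) and
  then from the swapped pair — the field's own direction still orients
  the contour. Zero-norm field patches are coasted across in the previous
  direction rather than aborting the walk.

### The delineation network

A compact encoder–decoder with skip connections maps the
intensity-normalised slice to 8 planes: per joint, two field components
(linear outputs, renormalised at use time) and two heatmaps (logistic
squashed). Both joints are predicted simultaneously. The full profile
resamples slices bicubically to 224×224 (zero-padding non-square slices on
the right/bottom so the aspect ratio of the content is preserved); the
desk profile runs the identical code path at 64×64.

The input carries two additional normalised coordinate channels. A
desk-scale network's receptive field cannot reliably tell the left from
the right joint, or a contour's superior end from its inferior end, from
local appearance alone — both ends of a joint line look alike — and
without absolute position the endpoint planes converge to multi-modal
blur. Coordinate channels resolve this directly.

Training uses Adam (learning rate 1e-3, betas 0.9/0.999) on an L2 field
loss plus a weighted L2 heatmap loss with per-pixel weight
`1 + alpha * target` (`alpha = 10` by default, 50 in the desk recipe,
countering the extreme foreground/background imbalance of endpoint maps),
the heatmap term additionally scaled by `heat_weight` (2 in the desk
recipe) to balance endpoint localisation against field regression in the
shared features. Augmentation applies one shared affine (translation
±20 %, scale ±20 %, rotation ±15°, left/right flips) to image and
landmarks and *regenerates* the targets from the transformed landmarks —
warping a vector field directly would corrupt its directions; flips also
swap the left/right output groups. Photometric noise and blur touch only
the image. An optional cosine learning-rate schedule is provided; the desk
recipe uses the constant default.

### The landmark baseline

The comparison network shares the same backbone but regresses 21 Gaussian
heatmaps per joint (42 planes), sparse annotations being up-sampled to 21
points by linear interpolation along the contour's arclength. Decoding
takes per-plane argmaxes in plane order. Contouring by field walking
yields denser, less aliased contours; on the synthetic bench it achieves
the lower mean closest-point RMS at the equal training budget.

### Evaluation

`closest_point_rms()` measures, for each ground-truth vertex, the distance
to the nearest predicted vertex, and returns the root mean square
(optionally in mm via the in-plane spacing; a symmetric variant exists but
the truth-to-prediction direction is the default, matching sparse expert
landmarks against dense walked contours). `error_quantiles()` summarises a
test set as empirical quantiles at a grid of data proportions, with
linear interpolation between order statistics (`stats::quantile` type 7).

## Stage 2: ROI extraction

The upper and lower extreme vertices of each joint, pooled over every
slice, define two lines (upper-left to upper-right, lower-left to
lower-right); the volume is rotated in the coronal plane by the mean of
their angles so both lines are near horizontal. One minimum bounding box
per joint — floor/ceil integer snapping, half-open — covers all slices'
vertices with no margin and is static across the volume. The same box
cuts both sequences (T1-weighted and STIR are assumed registered at ROI
resolution; only shape equality is asserted). Left crops are mirrored to
the canonical right-joint orientation, with the flag recorded; the
alignment angle is estimated once (on the T1-derived contours) and applied
to both sequences.

## Stage 3: multi-reader lesion classification

Five binary lesions are scored: bone marrow oedema, fatty lesions and
erosions per quadrant (upper/lower ilium, upper/lower sacrum), sclerosis
and ankylosis per joint — 14 tasks per SIJ, 28 per left-right pair. A
shared convolutional encoder embeds every slice of each sequence's crop;
slice embeddings are mean-pooled, the T1 and STIR embeddings concatenated,
and 14 linear heads produce per-task class probabilities. The embedding
pools the final feature map onto a 2×2 spatial grid rather than a global
average: quadrant-level lesions are *located*, and a translation-invariant
global pool would erase exactly the information those heads need. Quadrant
tasks are predicted from the whole joint crop (no quadrant cropping).

### The annotator model

Clinical-trial grading offers many labels per finding: here two readers,
three blinded sessions each (or three readers, one session). Labels
disagree, and a single "clean" target does not exist. Each reader,
session, and consensus level is modelled by a **rank-1 annotator matrix**
`A = a ⊗ b` applied as `B p` with `B = I + A`: the identity recovers the
model's own prediction, and two C-vectors per node (C = 2) keep the
parameterisation minimal. The vectors pass through a tanh squashing to
(−0.5, 0.5) so `B` stays near the identity and `B p` near the simplex
(outputs are clamped at 1e-6 and renormalised); the raw trace regulariser
is otherwise unbounded below.

Nodes are arranged in the **consensus tree**: base prediction → root
(inter-reader consensus) → per-reader (intra-reader consensus) → per
session. Cross-entropy is collected wherever a label exists: session nodes
against raw session labels, reader nodes against intra-consensus labels
(defined only when a reader agrees with themselves across all sessions),
the root against inter-consensus labels (all readers, all sessions
unanimous). Disagreement yields a missing consensus, never a majority
vote. The loss adds the summed traces of all annotator matrices, weighted
by `lambda` (default 1): `total = CE + lambda * trace`.

Two training details matter:

* **Scale of the trace term.** The trace enters once per batch against the
  *summed* cross-entropy (equivalently `lambda / n` against the mean).
  Adding it once per observation would bias each absorbed flip rate upward
  by roughly `2*lambda*rho*(1-rho)` — enough to destroy parameter
  recovery.
* **Initialisation.** `a = b = 0` is a saddle of the rank-1
  parameterisation (every gradient of `a` is proportional to `b` and vice
  versa), so fitted trees start from small random vectors. Explicitly
  constructed trees stay at the identity.

At inference the root-node prediction is the estimate compared against
inter-consensus labels. Evaluation excludes samples without consensus;
metrics are AUC (rank statistic, midranks for ties), sensitivity and
specificity at the operating threshold (0.5 by default) and balanced
accuracy, their mean. Cross-validation splits per patient, so all scans of
a subject share a fold.

## The synthetic test bed

No clinical data ships with the package; a generator emulates the
structures the pipeline consumes, and every generator is a pure function
of its specification and seed.

* **Slices** (`make_slice()`): two smooth, roughly vertical open contours
  left and right of centre (smoothed random-walk lateral offsets, gentle
  arc, vertex counts within the annotation range, each side clamped to its
  own half so contours never cross), rendered as dark joint-space bands on
  a brighter background with blur and Gaussian noise; per-side absence
  with probability 0.1 emulates joints outside the field of view.
* **Volumes** (`make_volume()`): contours drift by a bounded displacement
  per slice across ~20 slices.
* **Lesions** (`make_lesion_dataset()`): latent truth per task (prevalence
  0.3 — high enough that both classes are populated at desk sample sizes)
  with localised regional intensity effects in a canonical crop geometry:
  oedema brightens a quadrant of the STIR crop, fatty lesions a quadrant
  of T1, erosions darken the joint margin of a quadrant, sclerosis darkens
  a band along the joint line, ankylosis bridges the joint line with
  bright signal in both sequences. Truths are recoverable from regional
  crop means by construction.
* **Readers** (`reader_model()`): session labels flip the latent truth
  independently per reader/session at per-reader rates (class-specific
  rates and an intra-reader correlation knob are available; the default is
  i.i.d. given truth, the simplest model with non-trivial consensus
  structure).

What passing the synthetic bench shows: the geometry, the field/walker
mechanics, the optimisation, the annotator-matrix recovery and the full
plumbing are correct, and the planted signals are learnable end to end.
What it does not show: performance on real MRI — real joint lines are
lower contrast, anatomy is variable, lesion appearance is far subtler than
regional mean shifts, and reader noise is not independent across sessions.

## Problem sizes and desk recipes

The package's benchmark experiments (used by the test suite and
`scripts/acceptance.R`) run at workstation scale, chosen so the full suite
completes on a single CPU:

* Walker recovery: 200 random simple polylines (4–21 vertices, vertex
  spacing ≥ 2 px) on 64×64 grids; recovery means closest-point RMS < 1 px.
* Delineation: 200 training and 40 held-out synthetic slices at 64×64,
  depth-3 width-16 network, 300 Adam steps at batch 8, no augmentation
  (12 epochs at this budget favour fitting over regularisation; the
  augmentation path is exercised separately), walker cascade with the
  robust endpoint decode at inference. The same budget trains the
  21-heatmap baseline. A short run occasionally locks an endpoint plane
  into a wrong mode; the robust endpoint decode absorbs most of the
  damage, and `delineator_health()` is provided to diagnose such runs on
  held-out annotated slices.
* Reader-noise recovery: 2000 samples, rates 0.10/0.25, 2 readers × 3
  sessions, full-batch Adam.
* Classification: 100 patients (200 joints), 32 px crops, 3 slices per
  sequence, depth-3 width-8 encoder; a 2-fold per-patient cross-fit (600
  steps at batch 8, learning rate 3e-3 per fold; the reproduction script
  uses 500) scores every joint held-out. Per-lesion AUC pools the lesion's quadrant tasks, which are
  exchangeable in the synthetic corpus, so each estimate rests on all
  consensus-labelled samples of that lesion.

The full-scale profiles (224 px inputs, deeper encoders) use the identical
code paths.

## Known limitations

* The delineator is trained per slice; no through-plane consistency is
  enforced beyond the shared ROI box.
* Presence detection uses a single threshold on the source peak;
  calibrating it on validation slices is left to the user.
* Annotator matrices are independent across tasks; with very few labelled
  samples per task, sharing structure across tasks could be preferable.
* T1↔STIR registration is assumed; only shape equality is checked.
* The walker's inertia/cascade options trade a small amount of corner
  accuracy for robustness on regressed fields; on analytic fields the
  plain walker is exact and remains the default.
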