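---
title: "Dual cross-attention fusion of nodule ratings and CT volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual cross-attention fusion of nodule ratings and CT volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(noduleca)
```

## The problem

Pulmonary nodules found on thoracic CT must be triaged into likely-benign
and likely-malignant. Two complementary sources of evidence exist for each
nodule: the image itself, and the structured ordinal ratings that
radiologists assign (subtlety, internal structure, calcification,
sphericity, margin, lobulation, spiculation, texture), plus the nodule
diameter. `noduleca` implements a classifier that encodes both sources as
token sequences and fuses them with a pair of cross-attention modules
running in opposite directions, together with the cohort-construction
rules, preprocessing, cross-validation protocol and metric suite needed to
train and evaluate it.

## Cohort construction

The cohort rules mirror standard practice for multi-reader thoracic CT
annotation sets:

* Nodules at least 3 mm in diameter with at least three readers are kept;
  both bounds are inclusive. Anything else is rejected with a recorded
  reason, never an exception, so a run over a large annotation dump
  completes and reports what it dropped.
* The label comes from the malignancy scores alone (ordinal 1–5 per
  reader): scores are averaged over the present readers and rounded to the
  nearest integer. Rounded 1–2 is benign (label 0), 4–5 malignant
  (label 1), and the intermediate 3 excludes the nodule from the cohort.
* Rounding ties (`.5`) go *up* by default. A single uniform rule matters
  because the tie cases sit exactly on the benign/excluded and
  excluded/malignant boundaries: mean 2.5 is excluded under half-up
  rounding but benign under banker's rounding. Both rules are exposed
  (`rounding = "half_up"` / `"banker"`) so cohort counts can be validated
  under either; half-up is the default because it never silently merges a
  tie into the even neighbour.
* When an attribute has exactly three of four reader values, the fourth is
  imputed as the rounded mean of the three, clamped into the attribute's
  ordinal range. With fewer than three present values the rule is not
  defined, and the package raises an error rather than guessing — an
  under-specified case should surface, not be absorbed.

The per-nodule feature container is a fixed 9 × 4 matrix: nine attribute
rows (the eight per-reader ordinals plus diameter, in a fixed order) by
four reader columns sorted by reader identifier, with an imputed fourth
column when only three readers annotated. Diameter is reported per nodule,
not per reader, so its value is replicated across the four columns to keep
the container rectangular. Malignancy is deliberately not a row: it is the
target.

Before entering the model, each attribute row is affinely rescaled to
[0, 1] using its *fixed* scale bounds (e.g. subtlety 1–5, calcification
1–6, diameter windowed at 0–40 mm), never data-derived statistics. This
keeps cross-validation folds independent of each other and makes the
scaling reproducible without access to the training data.

## Volume preprocessing

CT volumes are Hounsfield-unit arrays with `(z, y, x)` axis order. The
pipeline is: trilinear resampling to isotropic 1 mm voxels, extraction of
a 32³ voxel cube centred on the voxel nearest the physical nodule centre,
then clipping to the [−1000, 400] HU lung window and affine mapping to
[0, 1]. Choices the pipeline fixes (all exposed as arguments):

* Interpolation is trilinear — the standard choice for CT intensity
  resampling; positions are clamped to the support so resampling an
  already-isotropic volume is an exact identity.
* Resampling happens *before* cube extraction, so the cube is always an
  isotropic 1 mm window regardless of the scanner's slice spacing.
* Out-of-volume voxels are padded with −1000 HU (air), the physically
  neutral fill; a flag records that padding occurred.
* Centre mapping uses nearest-voxel rounding of
  `(centre − origin) / spacing`; a centre outside the volume is an error
  naming the nodule.

## The model

Let `S` be the 9 × 4 rescaled rating matrix and `C` the 32³ normalized
cube. The forward pass is:

1. **Structured embedding.** Each attribute row of `S` passes through two
   stacked affine maps, 4 → 32 → `d` (default `d = 256`), with a ReLU on
   the output: nine non-negative tokens. The maps are applied row-wise as
   right-multiplications — the only reading consistent with the weight
   shapes (a 4 × 32 matrix cannot left-multiply a 9 × 4 one).
2. **Volume embedding.** `C` is split into its 32 axial slices; one shared
   convolution with a full 32 × 32 kernel (stride 32, 256 channels) maps
   each slice to a single token. Because the kernel covers the whole
   slice, this is a shared linear map of the flattened slices; slice order
   is preserved.
3. **Encoders.** Each token sequence runs through its own stack of six
   pre-norm transformer encoder blocks (self-attention + feed-forward,
   residuals, layer norm). Internals the architecture does not pin down
   are set to common defaults and exposed in `model_config()`: 8
   self-attention heads, feed-forward width `4d`, GELU, dropout 0.1, a
   final layer norm, and learnable positional embeddings added before
   encoding (slice order and attribute identity both carry information;
   positional signal can be switched off).
4. **Dual cross-attention.** Two *independent* single-head scaled
   dot-product attention modules with `d`-dimensional projections and
   scaling `1/sqrt(d)`: one uses image queries over structured keys/values
   (producing a 32 × `d` sequence), the other structured queries over
   image keys/values (9 × `d`). The naming in the code keeps the
   convention of the fusion equations even though it reads
   counterintuitively: the "structured" fused sequence is the one produced
   by image queries. Cross-attention is single-head with no output
   projection and no residual connection, exactly as the fusion equations
   are written; the subsequent layer norm applies directly to the attended
   sequence.
5. **Pooling and fusion.** Each attended sequence is layer-normalized per
   token (learned gain/offset) and mean-pooled over its tokens — pooling
   over the token axis is what yields two `d`-vectors whose concatenation
   (structured first) has length `2d`, matching the two-class linear head
   that follows. Training minimizes cross-entropy; benign is index 0 and
   malignant index 1, with malignant the positive class throughout.

### Ablations

`model_config(ablation = ...)` switches the exact variants used in the
component analysis: `structured_only` / `image_only` drop the other branch
and classify from the single pooled vector; `no_transformer` replaces both
encoder stacks (including their positional embeddings) with the identity;
`no_cross_attention` pools the encoded sequences directly. Only the
parameters an ablation uses are created, so checkpoints are unambiguous.

### Gradients and optimization

No automatic-differentiation framework is used: every layer carries a
hand-written reverse-mode gradient, verified in the test suite against
central finite differences (relative error below 1e-4 on a small
configuration) and against explicit-loop forward oracles (1e-6). A
mini-batch travels as one stacked token matrix so all token-wise algebra
runs as single BLAS calls; attention operates on per-sample row blocks and
never mixes tokens across samples, which is itself tested (a batched
forward pass equals the single-sample passes).

The training protocol defaults are 30 epochs, batch size 100, learning
rate 5e-4 and weight decay 1e-3. The optimizer is AdamW: weight decay is
named explicitly in the protocol while the optimizer is not, and the
decoupled formulation is the standard way to honour an explicit decay;
`adam` and `sgd` remain available for comparison. Weights are initialized
with uniform fan-in scaling under a recorded seed; the final epoch's
weights are kept (no validation split, no early stopping, except for an
optional training-accuracy stop used by capacity checks). All randomness —
initialization, batch shuffling, dropout — derives from one seed per fold,
so reruns are bit-identical on the same platform.

## Cross-validation and metrics

`cross_validate()` partitions the cohort into five folds, trains one model
per fold on the other four and scores the held-out fold. Folds are
stratified by label by default: the protocol's "random partition" is kept
available (`stratified = FALSE`), but stratification preserves the
benign/malignant ratio per fold to within one sample, which is what makes
per-fold metrics comparable at these cohort sizes. The headline summary is
the arithmetic mean of the per-fold metrics — matching a protocol that
averages metrics across iterations — while the pooled-confusion-matrix
metrics are also reported for comparison.

The metric suite is computed from the confusion matrix with malignant as
positive: accuracy, precision, sensitivity (= recall), specificity, and F1
(harmonic mean of precision and sensitivity). A metric whose denominator
is zero (e.g. precision under an all-benign predictor) is reported as `NA`,
never silently as 0. The suite is tested exactly against an independent
reference implementation on a thousand random confusion matrices.

## The synthetic generator

Real thoracic CT cohorts cannot ship with the package, so
`gen_dataset()` generates the same per-nodule containers the preprocessing
pipeline emits: a normalized 32³ cube, a 9 × 4 rating matrix, and a 0/1
label, written in the same on-disk layout so downstream code cannot tell
the two apart. Defaults mirror the study cohort's shape: 684 nodules, 330
malignant.

One knob, `delta` in [0, 1], scales *every* class-conditional difference:

* cubes: malignant nodules get a radius shift (+2.5 mm at `delta = 1` on
  a ~6 mm base), narrow radial spikes (spiculation) and wide boundary
  bumps (irregular margin), all with amplitude proportional to `delta`;
* ratings: latent means of the spiculation (+2.5), lobulation (+2),
  margin (−2) and diameter (+10 mm) rows shift by `delta` times those
  amounts, with nodule-level variation (sd 0.4) and per-reader jitter
  (sd 0.7 ordinal steps) before rounding and clamping.

At `delta = 0` the two class-conditional distributions coincide exactly —
the generator draws the same random variates for both labels — giving a
true null dataset on which any classifier should sit at chance. Signal is
injected into the two modalities with independent noise, so the
multimodal-versus-unimodal comparison is a real test of fusion rather
than of two redundant copies of one feature. The generator makes no
attempt at radiologically realistic texture: passing tests show the
pipeline learns and evaluates correctly under controlled separation, not
that it reaches any particular accuracy on clinical data.

The noise scales (voxel noise sd 0.05 on a [0, 1] intensity scale, reader
jitter 0.7 ordinal steps, nodule-level latent sd 0.4) were chosen once as
plausible magnitudes for screening CT and multi-reader ordinal ratings,
and are deliberately not tuned: at `delta = 1` they leave the classes
clearly separable, at `delta = 0` nothing is.

## Problem sizes used in the checks

The test suite and the acceptance script run, as the package's own
standard conditions: reduced five-fold cross-validation (width 64, 2
blocks per encoder, 10 epochs) on 300 synthetic nodules at 50% prevalence
for the separation and null checks and for the unimodal ablations; the
full-width model (256, 6 blocks) on 20 samples for the overfit-capacity
check, stopping once training accuracy reaches 1 within a 200-epoch cap;
and scaled-down token dimensions for the oracle-equivalence checks. The
full-cohort, full-protocol configuration (684 nodules, 30 epochs) is the
default of the exported functions.

## Known limitations

* Reproducing the published cohort counts and headline accuracies requires
  the real LIDC-IDRI/LUNA16 data and full training; nothing in this
  package's checks depends on protected data.
* The XML reader consumes a *clustered* LIDC-style layout (reader contours
  already grouped into nodules, with per-nodule diameter and centre, as
  LIDC tooling provides); it does not re-cluster raw two-phase contour
  files, and DICOM series must be converted to NIfTI or serialized
  volumes upstream.
* "At least three readers" is implemented as a count of annotating
  readers, not as an agreement criterion — the natural reading, but one
  that should be validated against external cohort counts when the real
  data is available.
* Training is single-threaded CPU matrix code: correct and reproducible,
  and fast enough for the reduced configurations above, but not a
  replacement for a GPU framework at full scale.
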