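---
title: "Methods: a desk-scale five-grade DR classification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale five-grade DR classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusdr)
```

## The problem

Diabetic retinopathy screening produces retinal fundus photographs graded
on a five-level severity scale (0 = No DR through 4 = Proliferative DR).
Two features of this data shape every design choice in the package.
First, the class skew is extreme: a screening population is dominated by
healthy eyes, with the severe grades contributing under 3% of images
between them. An unweighted classifier trained on such data collapses to
predicting grade 0. Second, individual deep classifiers disagree most on
exactly the rare grades, which makes an ensemble attractive — but a plain
average gives a weak classifier the same say as a strong one.

The package implements the full pipeline around these two problems:
geometric preprocessing, minority-class upsampling with a closed-form
plan, a classifier contract with attention and two-phase transfer
learning, F1-weighted soft voting with a tunable amplification parameter,
and the multiclass metrics needed to judge the result. Everything runs at
desk scale on synthetic data so the machinery itself is testable.

## Preprocessing

Photographs arrive with a black frame around a roughly circular eye
region. `preprocess_fundus()` applies four steps in order: trim border
rows/columns whose pixels all fall below intensity 7, zero everything
outside the inscribed circle whose diameter is the smaller image side,
trim again, and resize to a square (default 299 px, bilinear).

Conventions the data does not dictate, fixed as follows:

* "Below 7" is strict (`< 7`), evaluated on the maximum across the three
  channels, so a single faint channel keeps a row. This is the
  conservative reading: it never discards a pixel that carries signal.
* Trimming is a bounding-box crop. Only *contiguous border* rows and
  columns are removed; deleting dark interior rows would shear the
  anatomy.
* Circle membership uses zero-based pixel centers, center
  `((H−1)/2, (W−1)/2)` and radius `min(H, W)/2`, with "inside" meaning
  distance ≤ radius. Sub-pixel conventions differ between libraries; this
  one makes the mask idempotent and exactly reproducible.
* The resize kernel is bilinear (via EBImage), under which a constant
  image stays constant — a property the tests rely on. Trimming is not
  iterated to a fixed point: one trim–mask–trim pass suffices because
  masking can only darken rows near the border of the crop.

The second trim matters for non-square crops: masking a tall crop blanks
entire rows at the top and bottom, which the re-trim then removes.

## The balancing plan

For minority class *i* with `Ni` training images against a majority class
of `N0`, every image receives

$$\mathrm{Add}_i = \left\lfloor \frac{N_0 - N_i}{N_i} \right\rfloor$$

transformed copies, so the class total becomes `Ni · (Add_i + 1) ≤ N0`.
The floor is forced by the arithmetic of the published counts this
formula reproduces (e.g. 15,472 majority vs 1,445 → 9 copies each, total
14,450). `balance_plan()` computes the table; the invariant
`0 ≤ N0 − Ni(Add_i + 1) < Ni` is property-tested.

Three transforms are admitted: left-right flip, up-down flip, and
rotation about the image center by an angle drawn uniformly from
[0°, 360°). How to allocate `Add_i` copies across them is not dictated by
the formula; the package uses the deterministic order *flip_lr, flip_ud,
then rotations*, because each flip can contribute at most one distinct
image per source. Rotations draw one independent angle per generated
image from a seeded generator, and duplicates of a flip are not re-drawn
(they are measure-zero events). Every generated image — not only the
rotations — is re-masked with `remove_unnecessary_area()`, since rotation
interpolation can push corner pixels above the dark threshold; for flips
of already-masked inputs this is a no-op. Translation-based upsampling is
deliberately excluded: translated eyes differ too much from real
acquisition geometry.

Class weights follow the inverse-frequency rule
`w_c = n_samples / (n_classes · count_c)`, whose count-weighted mean is
exactly 1. The training loss multiplies each example's cross-entropy by
its grade's weight, so a minority example contributes exactly `w_c` times
an unweighted one — a property checked on single gradient steps.

## Splitting

`split_311()` divides a manifest 3:1:1. The rounding rule is ceil for
validation and test (`ceiling(N/5)` each) with the remainder to training;
this is the only rule consistent with the reference sizes the tests pin
(35,126 → 21,074 / 7,026 / 7,026, where naive rounding would give 21,076
training images). Assignment is a seeded per-class shuffle with
largest-remainder allocation of each class's holdout against the exact
global totals, keeping every class's training share within one image of
3/5. Stratification is a package decision made for stability on skewed
data; a non-stratified split of the same sizes is a special case users
can approximate with a single-class manifest.

## The classifier contract

A base classifier is: backbone without its top → attention block →
global average pooling → dense softmax over the grades. Backbones are
opaque feature extractors behind a registry; the five large ImageNet
architectures are recognized names a user can plug an implementation
into, and `tiny_test` — two 3×3 convolution + ReLU + 2×2 average-pool
stages, ~1.7k parameters — is built in so the whole pipeline trains in
seconds on one CPU.

The attention block applies channel gating then spatial gating. Channel
gating pools the feature map spatially (mean and max), pushes both
descriptors through a shared two-layer bottleneck (reduction 4), sums,
and squashes with a sigmoid; spatial gating stacks the channel-wise mean
and max maps, convolves 7×7, and squashes. Both gates lie in (0, 1), so
the block only attenuates, preserves shape, and maps zero to zero —
the contract the tests check. Its parameters are part of the added top
and therefore train in phase 1.

Training follows the freeze-then-fine-tune schedule: phase 1 optimizes
only attention + head with the backbone frozen (bit-identical before and
after, by construction and by test); phase 2 unfreezes everything at a
lower rate. The optimizer is Adam; nothing in the contract prescribes
learning rates, epochs or batch size, so `train_config()` exposes them
all (defaults 1e-3 / 1e-5, 5 + 3 epochs, batch 16 — conventional
fine-tuning values). Gradients are explicit (im2col convolutions) and
verified against numerical differentiation in the test suite. After
phase 2 the validation macro-F1 is recorded: the downstream weighting
needs one scalar per classifier, "F1" alone does not pin an aggregation
for a five-class task, and macro-F1 is the choice consistent with the
pipeline's emphasis on rare grades.

## Weighted soft voting

Classifier *i* with validation score `F1_i` receives

$$\lambda_i = \frac{F1_i}{\sum_p F1_p} + \left(F1_i - \overline{F1}\right) n$$

The deviations from the mean sum to zero, so `Σλ = 1` identically for
every `n ≥ 0` — verified to 1e−12 over a thousand random panels. The
amplification parameter `n` widens the gap between strong and weak
classifiers: λ of an above-mean classifier is strictly increasing in
`n`, below-mean strictly decreasing. For large `n` a weak classifier's λ
goes negative; the formula is applied verbatim (the fused argmax remains
defined) and a classed warning is emitted, because silently clipping
would break `Σλ = 1`.

Fusion is `Σ λ_i P_i` over the per-classifier probability matrices, and
the prediction is the argmax grade with ties broken toward the lower
grade (the conservative direction for a severity scale; the convention
is otherwise arbitrary and is documented rather than hidden).

`select_n()` evaluates a coarse grid (10, 20, …, 100) then a fine grid
(1, …, 10) and returns the `n` maximizing macro-F1, with accuracy and
then the smaller `n` as tie-breakers. Selection scores the **validation**
probability matrices: scoring the test set would leak the final
evaluation into a tuning choice. Large `n` degrades both metrics because
the fused distribution becomes a near-copy of the single strongest
classifier, which is why the fine grid sits below the coarse one.

## Metrics

All per-class scores are one-vs-rest: precision `TP/(TP+FP)`, recall
`TP/(TP+FN)`, specificity `TN/(FP+TN)`, F1 the harmonic mean. Zero
denominators yield 0 (the conservative convention; an undefined precision
for a never-predicted class should hurt, not propagate NaN). ACA is the
mean of the row-normalized confusion diagonal — balanced accuracy, the
headline number for skewed data. Micro-F1 pools counts globally and
equals accuracy for single-label multiclass, an identity the tests assert
exactly. AUC is macro one-vs-rest with midrank ties, checked against
exhaustive pair counting and against pROC. The per-class report table
writes recall in its "accuracy" column, mirroring the layout common in
screening papers; the aggregate row carries the true accuracy.

## Synthetic data

`make_fundus()` emulates what preprocessing and balancing actually
consume: a frame of noise strictly below intensity 7, a bright elliptical
disc (random eccentricity, to exercise non-square trimming), a gentle
radial falloff, a reddish channel tint, and optional bright lesion blobs.
When a grade is supplied, it shifts the disc intensity (+18 per grade)
and adds `grade` lesions, giving desk-scale classifiers a learnable
signal whose difficulty (adjacent grades overlap) roughly mimics the
ordinal structure of severity grading. The defaults (64 px canvas, 6 px
border, base intensity 100–135) were chosen once so that a linear probe
on mean intensity reaches ~50% five-class accuracy — hard enough to be
non-trivial, easy enough for a tiny CNN.

What the generator does **not** emulate: vessel trees, optic discs,
illumination gradients, camera artifacts, label noise, or any biological
lesion morphology. Passing tests therefore demonstrate that the pipeline
machinery is correct and that its statistical components behave as
designed — not that any backbone generalizes to real retinas.

`make_prob_matrices()` provides skill-controlled classifier panels for
ensemble tests: classifier *i* picks the true grade with probability
`skills[i]`, otherwise a uniform wrong grade, and concentrates a fixed
probability mass on its pick. Empirical F1 is monotone in skill (tested),
so planted skill gaps are recoverable.

## Pipeline and problem sizes

`run_pipeline()` chains synth → preprocess → split → balance → train →
n-search → fuse → report, writing each stage's artifacts under a run
directory. The shipped defaults are desk-scale choices: 82 synthetic
images (52/8/12/5/5 — the screening skew, with a floor of five per grade
so every grade reaches all three splits), 32 px canvases, three
`tiny_test` classifiers, 15 + 5 epochs at 0.05 / 0.005. A default run
finishes in about a minute on one CPU; the test suite's smaller
configurations run in seconds. Users with real data and GPU backbones
swap `data_dir`/`manifest` and `classifiers` in `run_config()` — the
bespoke arithmetic (plan, λ, n-search, metrics) is identical at any
scale.

## Known limitations

* The built-in trainer is single-threaded and per-image; it is meant for
  contract verification and desk-scale experiments, not production
  training. Real backbones arrive via `register_backbone()` with their
  own training machinery behind the same `forward`/`backward` closures.
* Negative λ at large `n` produce fused "probabilities" outside [0, 1];
  the package warns instead of renormalizing.
* ACA requires every true grade present; tiny validation subsets may
  lack one, so the n-search scores macro-F1 over the grades present.
* The split guarantees sizes and stratification, not any particular
  membership; reproducing an external split exactly requires its
  original assignment list.
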