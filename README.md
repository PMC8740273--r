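# fundusdr

A desk-scale R toolkit for building and evaluating five-grade diabetic
retinopathy (DR) classification pipelines from retinal fundus photographs.
It is aimed at researchers who want the *pipeline machinery* — image
preprocessing, class-imbalance handling, an attention-augmented classifier
contract with two-phase transfer learning, F1-weighted soft-voting
ensembling, and multiclass evaluation — in a form they can test end to end
on one CPU with synthetic data, and then scale up by plugging real
backbones and real photographs into the same interfaces.

DR severity is graded 0–4 (No DR, Mild, Moderate, Severe, Proliferative).
Screening datasets are heavily skewed toward grade 0, and single deep
classifiers disagree on the rare late grades; the toolkit addresses both.

## What it implements

**Preprocessing.** Each photograph is cropped to remove contiguous border
rows/columns whose pixels are all darker than 7 (on the channel maximum),
masked to the inscribed circle whose diameter is the smaller of height and
width, re-cropped, and resized (bilinear) to a square, 299 px by default:

```r
preprocess_fundus(img, preprocess_config(dark_threshold = 7, target_side = 299))
```

**Class balancing.** For minority class *i* with *Nᵢ* training images
against the majority's *N₀*, each image receives

    Addᵢ = ⌊(N₀ − Nᵢ) / Nᵢ⌋

transformed copies — a left-right flip, an up-down flip, then independent
random-angle rotations — each re-masked to the circular eye region.
Inverse-frequency class weights `n_samples / (n_classes · count(c))` are
available for the training loss.

**Classifiers.** A backbone feature extractor (opaque and pluggable; a
tiny built-in CNN trains in seconds) followed by a channel-and-spatial
attention block, global average pooling and a softmax head, trained in two
phases: head+attention only with the backbone frozen, then everything
unfrozen at a lower learning rate. Validation macro-F1 is recorded.

**Weighted soft voting.** Classifier *i* with validation score F1ᵢ gets

    λᵢ = F1ᵢ / Σₚ F1ₚ + (F1ᵢ − mean(F1)) · n

so Σλᵢ = 1 for every amplification parameter *n* ≥ 0; fused probabilities
are Σᵢ λᵢ·Pᵢ and the prediction is the argmax grade. *n* is chosen by a
two-stage grid search (10…100 then 1…10) on validation macro-F1.

**Evaluation.** Per-class precision / recall / specificity / F1, accuracy,
ACA (mean of the row-normalized confusion diagonal), macro-F1, micro-F1
(= accuracy for single-label tasks) and macro one-vs-rest AUC with midrank
ties.

## Worked example

The published balancing table for a 15,472-vs-minorities training set is
reproduced by:

```r
library(fundusdr)
balance_plan(15472, c(1445, 3183, 553, 421))
#> # A tibble: 4 × 4
#>   class count add_per_image total
#>   <int> <int>         <int> <int>
#> 1     1  1445             9 14450
#> 2     2  3183             3 12732
#> 3     3   553            26 14931
#> 4     4   421            35 15156
```

Each image of the 553-image class gets 26 transformed copies, lifting the
class to 14,931 images — just under the majority's 15,472, as intended.
Fusion weights for a five-classifier panel at n = 3:

```r
tidy(compute_lambdas(c(0.87, 0.88, 0.88, 0.87, 0.87), n = 3))
#> # A tibble: 5 × 3
#>   classifier    f1 lambda
#>        <int> <dbl>  <dbl>
#> 1          1  0.87  0.187
#> 2          2  0.88  0.219
#> 3          3  0.88  0.219
#> 4          4  0.87  0.187
#> 5          5  0.87  0.187
```

The 0.01 F1 edge of classifiers 2–3 is amplified into a 0.032 weight gap;
the weights still sum to 1. A complete end-to-end run on synthetic
photographs (three tiny base classifiers, ~1 minute on one CPU):

```r
run <- run_pipeline(run_config(seed = 11))
run
#> Five-grade DR pipeline run
#>   panel:       3 base classifiers
#>   val F1:      0.363, 0.309, 0.297
#>   chosen n:    1
#>   ensemble test accuracy: 0.647  (best single: 0.647 )
glance(run$metrics)   # accuracy, ACA, macro/micro-F1, AUC on the test set
```

The run directory holds every stage artifact: split manifests, trained
model directories, per-classifier test probability CSVs, the n-search
score table, the λ report and a per-class report table.

A thin command-line wrapper with per-stage subcommands
(`synth`, `preprocess`, `split`, `balance`, `ensemble`, `run`) is
installed as `exec/drpipe`.

## Limitations

The synthetic generator emulates the gross geometry of fundus photographs
(dark frame, bright elliptical disc, lesion blobs), not retinal biology;
desk-scale accuracy figures say nothing about performance on real
screening data. The five large ImageNet backbones are registry slots for
user-supplied implementations, not bundled networks. See the methods
vignette (`vignettes/dr-pipeline-methods.Rmd`) for the full account of
the model, parameter choices and numerical conventions.
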