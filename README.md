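# hemadapt

Parameter-efficient adapter fine-tuning for **hematoma segmentation on
non-contrast head CT**, implemented end to end in R. The package is aimed at
researchers who want to study the *mechanics* of adapter-based transfer
learning for medical image segmentation — preprocessing, model, losses,
metrics, statistics — on a desk-scale, fully synthetic test bed, with no
clinical data, GPU, or external pretrained weights.

## What it implements

**Preprocessing.** Stored DICOM values are converted to Hounsfield units by
the linear rescale `x_HU = x · slope + intercept`, contrast-adjusted with the
piecewise window

```
f(x) = 0                                   x_HU ≤ lower
     = 255 (x_HU − lower)/(upper − lower)  lower < x_HU < upper
     = 255                                 x_HU ≥ upper
```

with default window `[0, 140]` HU (acute blood is hyperdense relative to
brain tissue), then orientation-standardized from second-order image
moments, zero-padded/cropped to a square target, and min–max normalized.

**Model.** A promptable segmentation architecture: a ViT image encoder
(`vit_b` = ViT-B/16 geometry, or a `tiny` desk preset), a sparse prompt
encoder for points and boxes, and a two-way cross-attention mask decoder.
Serial bottleneck adapters

```
Adapter(x) = W_up · ReLU(W_down · x + b_down) + b_up + x ,
W_down ∈ R^{d×m}, W_up ∈ R^{m×d}
```

are inserted after the attention and MLP sub-layers of every transformer
block. With `d = 768`, `m = 100` and both placements, the `adapters_only`
freezing policy trains **3,707,232** parameters (3,686,400 without biases) —
under 4M, versus ~86M for the full base encoder. Everything runs on a small
reverse-mode autodiff engine written in R, so adapters (and optionally the
decoder) can be trained on CPU.

**Losses.** BCE, soft Dice, Focal Tversky `(1 − TI)^γ` with
`TI = (TP + ε)/(TP + αFP + (1−α)FN + ε)`, and the distance-map boundary loss
`mean(sdm(GT) · p)`, plus weighted combinations such as `BCE(50%) + BL(50%)`.

**Metrics.** Slice- and scan-level Dice, IoU, 95th-percentile Hausdorff
distance on 4-/6-connected boundaries, accuracy/sensitivity/specificity, and
volumetric similarity `VS = 1 − ||P|−|GT||/(|P|+|GT|)`, with the fold-wise
aggregation conventions (mean of fold means ± sd of fold means at slice
level; ± mean of fold sds at scan level).

**Experiments & statistics.** Stratified 20% test split plus stratified
k-fold cross-validation, an AdamW training loop with checkpointing and exact
resumption, percentile-bootstrap CIs, and the Friedman test
(`χ²_F = 12/(nk(k+1)) ΣR_j² − 3n(k+1)`) gatekeeping a Nemenyi post-hoc with
critical difference `CD = q_{α,k} √(k(k+1)/6n)`.

**Inter-observer analysis.** Reviewer-vs-reviewer / reviewer-vs-model
agreement tables, binned by lesion size (0–2000, …, ≥8000 positive pixels).

**Synthetic phantoms.** A seeded generator producing head-CT-like scans
(skull ring ≈900 HU, brain ≈30 HU, smooth lesion blobs at 50–90 HU,
Gaussian noise, per-scan DICOM rescale metadata) with exact ground-truth
masks and a correlated second annotator; written to real DICOM series plus
NIfTI masks so the whole I/O path is exercised.

## Worked example

```r
library(hemadapt)

# a 10-scan phantom dataset
ds <- generate_phantom_dataset(phantom_spec(n_scans = 10, image_size = 64,
                                            fraction_positive = 0.8, seed = 11))
dataset_statistics(ds)
#> # A tibble: 1 × 7
#>   scans_pos scans_neg slices_pos slices_neg   q25   q50   q75
#>       <int>     <int>      <int>      <int> <dbl> <dbl> <dbl>
#> 1         8         2         16         64  106.  174.   213

# preprocess one scan: HU -> window [0,140] -> size -> [0,1]
pr <- preprocess_scan(ds$scans[[1]]$volume, mask = ds$scans[[1]]$gt, target = 64)

# the adapter parameter budget of the full-size configuration
m <- build_model(model_preset("vit_b"), init = "zeros")
insert_adapters(m, adapter_config(m = 100))
freeze_policy(m, "adapters_only")
count_trainable_params(m)
#> [1] 3707232

# two-stage run: pretrain the tiny preset on a synthetic corpus, then
# fine-tune on the experimental phantoms and evaluate held-out Dice
ck <- tempfile(fileext = ".rds")
phantom_pretrain(checkpoint = ck)          # the reference checkpoint (~4 min)
phantom_learning_demo(seed = 1, pretrained = ck)
#> # A tibble: 1 × 5
#>    seed n_train_slices untrained_dice trained_dice final_loss
#>   <int>          <int>          <dbl>        <dbl>      <dbl>
#> 1     1             41        0.00351        0.728    -0.00554
```

`dataset_statistics()` reports the positive/negative composition and the
quartiles of lesion footprints (pixels per positive slice);
`phantom_learning_demo()` shows the learning signal: a randomly initialized
model scores near zero on held-out positive slices, the
pretrained-then-fine-tuned one recovers most of the lesion area
(`trained_dice` 0.5–0.86 depending on the seed; the slightly negative final
loss is the boundary-loss component, which is sign-indefinite).

The full pipeline — simulate → preprocess → split → train → evaluate →
compare → agreement — is driven by one config:

```r
res <- run_pipeline(default_run_config(seed = 1))
```

or from the shell:

```sh
Rscript scripts/hemadapt.R all --seed 1 --output runs/demo
```

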