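---
title: "Adapter-based hematoma segmentation: models, losses, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adapter-based hematoma segmentation: models, losses, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hemadapt)
```

## The problem

Acute intracranial hematoma appears hyperdense (roughly 50–90 HU) on
non-contrast head CT, against brain tissue near 30 HU and bone near
1000 HU. Delineating it slice by slice is slow and shows substantial
inter-observer variability, which motivates automatic segmentation.
`hemadapt` implements a parameter-efficient strategy: a promptable
vision-transformer segmentation architecture in which small bottleneck
*adapters* carry the task-specific learning while the backbone can stay
frozen. Because clinical CT datasets and released pretrained weights cannot
ship with a package, every component is exercised on synthetic head
phantoms; this vignette explains the modelling choices, their assumptions,
and exactly what the desk-scale experiments do and do not demonstrate.

## Preprocessing

The pipeline order is: Hounsfield conversion → window/level contrast →
orientation standardization → size standardization → min–max normalization.

* **Hounsfield conversion** applies the DICOM rescale `x·slope + intercept`
  elementwise. Missing rescale metadata is an error, never a silent default.
* **Windowing** uses a `[0, 140]` HU default: wider than the usual brain
  window (`[0, 80]`) because blood is brighter than brain tissue; the output
  is kept in floating point through the pipeline and quantized to `uint8`
  only on export, avoiding a double rounding before normalization.
* **Orientation** is estimated with no learned component: threshold the HU
  volume at 100 HU (bone), compute per-slice second-order image moments,
  take the angle of the principal axis against the vertical, and combine
  slices by a circular median. The affine rotation uses bilinear resampling
  for images and nearest-neighbour for masks so masks stay binary.
  Coordinates are pinned package-wide: (row, col) indexing, origin top-left,
  angles counter-clockwise positive as displayed.
* **Size standardization** pads symmetrically with zeros (odd differences
  put the extra pixel bottom/right — an arbitrary but fixed convention that
  makes tests bit-exact) and center-crops larger slices.
* **Min–max normalization** maps a constant slice to all zeros rather than
  dividing by zero; a constant slice carries no information either way.
* **Augmentation** (training only) applies horizontal flip, rotation
  (±15°), zoom (0.9–1.1), shift (±10%) and brightness/contrast jitter
  (±20%), each independently with probability 0.5, geometric transforms
  shared between image and mask. The ranges are mild, in line with common
  medical-imaging practice, and fully seeded.

Whether contrast adjustment should precede or follow the affine transform is
not settled; the pipeline windows first (the order above), which cannot
change the mask geometry and only affects interpolation of already-clipped
intensities.

## Model

The architecture has three parts:

* an **image encoder**: a standard pre-norm ViT. `vit_b` reproduces the
  ViT-B/16 geometry (1024 px input, patch 16, d = 768, 12 blocks, heads 12,
  four uniformly spaced global-attention blocks; the remaining blocks use
  local windowed attention with window side `grid/4`, min 2). The `tiny`
  preset (64 px, patch 8, d = 64, 4 all-global blocks, 2 heads) is the
  desk-scale workhorse: one forward+backward pass takes well under a second
  on one CPU core.
* a **sparse prompt encoder**: points and box corners are embedded with a
  random-Fourier positional encoding plus a learned per-type embedding; an
  empty prompt set yields a learned padding token.
* a **two-way mask decoder**: blocks of token self-attention,
  token→image and image→token cross-attention with pre-norm MLPs; the image
  embedding is upsampled by two learned pixel-shuffle stages; a hypernetwork
  MLP turns the mask token into a dynamic per-pixel linear classifier, and
  the resulting logit grid is bilinearly upsampled to input resolution. The
  output head carries a scalar logit bias initialized at −2, i.e. a ~10%
  foreground prior: without it, early training must first crush a
  half-probability field to background, a phase that tends to overshoot
  into an all-background collapse. A single mask output is produced — the
  task is binary, so no ambiguity head is needed.

**Adapters.** Each transformer block receives serial bottleneck adapters
immediately after its attention and MLP sub-layers:
`W_up ReLU(W_down x + b_down) + b_up + x`. Down-projections are initialized
with small random weights, up-projections with zeros, so an adapted model is
*exactly* functionally identical to the unadapted one at initialization —
a property the test suite asserts bitwise. Biases are included by default
(both variants satisfy the sub-4M parameter budget) and can be switched off.

**Freezing policies.** `adapters_only` reflects the quantified claim that
fine-tuning touches fewer than 4 million parameters; because the written
record is ambiguous about whether the decoder was also updated,
`adapters_plus_decoder` is available as a configuration switch, and `full`
trains everything. For the desk-scale experiments that start from *random*
initialization (no pretrained backbone exists inside the package),
`adapters_only` is not meaningful — there is nothing pretrained to
preserve — so the learning demonstration uses `adapters_plus_decoder`.

**Prompts.** No prompt protocol is stated for the original experiments. The
package defaults to deterministic, non-interactive prompts: a tight
ground-truth bounding box (dilated 3 px) is available for prompted training,
and a whole-image box gives fully automatic operation; the learning
demonstration uses the whole-image box for both training and inference so
that train and test conditions match.

**Why a native autodiff engine?** No deep-learning framework is available
to R in this project's dependency set, and the training loop is part of
what the package must demonstrate. The engine is a small tape-based
reverse-mode differentiator over base-R matrices (BLAS-backed), with
finite-difference tests for every operator and for the whole model. It is
adequate for the tiny preset; it is not a GPU substitute, and the `vit_b`
preset is built for parameter accounting and weight loading, not for
training inside tests.

## Losses

* **BCE** — mean binary cross-entropy, the default.
* **Soft Dice** — `1 − (2Σpy + s)/(Σp + Σy + s)`, smooth `s = 10⁻⁶`.
* **Focal Tversky** — `(1 − TI)^γ` with
  `TI = (TP + ε)/(TP + αFP + (1−α)FN + ε)` on soft counts, defaults
  `α = 0.4, γ = 1, ε = 0.01`. Several published variants exist (where ε
  enters; `(1−TI)^γ` vs `(1−TI)^{1/γ}`); this form is pinned, and with
  `γ = 1` the distinction vanishes. The index is clamped before
  exponentiation because this loss is prone to gradient blow-ups when the
  index fluctuates.
* **Boundary loss** — the cited combination partner is the distance-map
  surface loss: mean over pixels of `sdm(GT) · p`, where the signed distance
  map is Euclidean distance to the 4-connected mask boundary, negative
  inside. Empty (full) masks get an all-positive (all-negative) map at the
  image-diagonal magnitude, with a warning, so negative slices stay finite.
  No epoch ramp is applied to the boundary weight.
* **Combinations** — printed percentage weights are normalized to sum to
  one, so `BCE(75%) + BL(25%)` means `0.75·BCE + 0.25·BL`.

Losses are evaluated on probabilities with analytic gradients; the training
loop clamps probabilities to `[10⁻⁷, 1−10⁻⁷]` *consistently* in the value,
the gradient, and the sigmoid chain rule, which keeps the BCE gradient with
respect to logits equal to `p − y` even deep in saturation. (An earlier
draft clamped only inside the loss; the mismatched chain rule silently
zeroed gradients at saturated pixels and made collapse unrecoverable — the
kind of defect only an end-to-end learning test catches.)

## Metrics and aggregation

Dice, IoU, 95%HD, accuracy, sensitivity, specificity per slice; the same
plus volumetric similarity per scan (3-D). Conventions, all pinned and
configurable:

* Both-empty pairs (negative slice, empty prediction) score Dice = IoU = 1
  and are excluded from Hausdorff aggregation with a logged count. This
  materially inflates slice-level means on negative-slice-rich data — one
  reason published slice-level accuracy columns approach 100% — so the
  convention is explicit rather than implicit.
* Boundaries are 4-connected (2-D) / 6-connected (3-D); a single-slice
  stack reduces to the 2-D definition.
* The 95th percentile uses R's type-7 (linear interpolation) rule over the
  *pooled* directed nearest-neighbour distances; percentile 100 recovers
  the classical Hausdorff maximum. Distances are in pixels unless voxel
  spacing is supplied (then mm).
* Spreads are sample (n−1) standard deviations. Slice-level summaries are
  mean of fold means ± sd of fold means; scan-level summaries are mean of
  fold means ± mean of fold sds.

## Experiments

`stratified_split()` holds out 20% of scans and partitions the rest into
five folds, stratified by scan positivity; per-fold positive quotas differ
by at most one. Training uses AdamW (lr 5·10⁻⁵, weight decay 0.1, batch
size 2, 50 epochs as defaults — the fine-tuning recipe), iterating all
training slices per epoch in a seeded shuffle, negative slices included.
"Decay rate 0.1" is interpreted as AdamW weight decay, not a learning-rate
schedule; no schedule is applied by default. Optional linear warmup and
global-norm gradient clipping are available for from-scratch training. The
final-epoch checkpoint is kept (best-validation selection is a config
option), and checkpoints store a flat name→array archive plus optimizer
state, so a resumed run reproduces an uninterrupted one bit for bit.

Statistical comparison follows the gatekept protocol: Friedman's rank test
over blocks (scans by default), using the plain `χ²_F` statistic with
average ranks on ties, then — only if `p < α` — a Nemenyi post-hoc with
`CD = q_{α,k}√(k(k+1)/6n)`. The `q_{α,k}` values come from the studentized
range distribution (`qtukey(1−α, k, ∞)/√2`), checked in the tests against
published table constants. Scan-level bootstrap CIs use the percentile
method.

## Synthetic phantoms: what they do and do not show

Each phantom scan is an elliptical skull ring (~900 HU) around brain tissue
(30 HU); lesions are thresholded sums of 2–4 Gaussians — smooth, irregular
blobs — painted at a uniform HU in 50–90, spanning 1–3 contiguous slices
with a tapered area profile; Gaussian noise (sd 4 HU) is added afterwards,
so ground-truth masks are exact. Stored values encode HU through a per-scan
random intercept in [−1100, −950] (slope 1), making the rescale conversion
non-trivial, and scans are written as real DICOM series. Default composition
is 80% positive scans with per-slice lesion footprints whose quartiles,
rescaled to the 64 px phantom grid, match the clinical size distribution
(tens to a few hundred pixels). The second annotator perturbs each lesion's
boundary morphologically (dilate/erode with radius ~|N(0, σ)|, σ = 2 px
default) and misses small lesions with probability 0.2 — enough structure
to reproduce the qualitative size-dependence of human agreement.

Passing the phantom experiments demonstrates that the pipeline's machinery
is correct and that the model class can extract a real segmentation signal
from CT-like intensity structure. It does **not** demonstrate clinical
performance: phantoms have no anatomy, no partial-volume or beam-hardening
physics, no annotation ambiguity beyond the simulated perturbation, and the
tiny preset has none of the pretrained knowledge that makes the full-scale
system competitive.

## The learning demonstration

`phantom_learning_demo()` is the package's standard desk-scale experiment,
and it mirrors the two-stage workflow of the full-scale system, in which
the model is never deployed from random weights.

Stage one (`phantom_pretrain()`) emulates public-data pretraining: a
separate phantom corpus with a broader lesion-size distribution (8 scans,
90% positive, lesions 60–400 px), trained from random initialization for
50 epochs with all parameters free — at this stage there is no pretrained
backbone to preserve, so the `adapters_only` policy is not meaningful.
From-scratch training needs its own recipe: AdamW at lr 1.5·10⁻³, batch
size 1, and a Dice-heavy BCE(25%) + Dice(75%) mixture that counteracts the
~25:1 background/foreground imbalance (at 5·10⁻⁵ a random initialization
barely moves in 50 epochs). The default seed and epoch count define one
*reference checkpoint*, playing the role of the released pretrained
weights: every fine-tuning run starts from the same checkpoint while the
experimental data and fine-tuning seeds vary.

Stage two generates the "experimental" dataset (10 scans, ~40 training
slices at 64 px across 8 scans, 2 positive scans held out) and fine-tunes
the pretrained weights for 20 epochs under the `adapters_plus_decoder`
policy with the reference fine-tuning recipe — AdamW lr 5·10⁻⁵, weight
decay 0.1, batch size 2, BCE(50%) + boundary(50%) loss — and whole-image
box prompts for both training and evaluation. The two recipes are not
interchangeable: fine-tuning a converged checkpoint at the from-scratch
rate destroys its features (classic catastrophic forgetting; we measured
held-out Dice collapsing from ~0.8 zero-shot to near 0 on most seeds),
which is precisely why a small fine-tuning rate is the norm for pretrained
backbones.

Held-out performance is the mean Dice over positive slices only — with
the both-empty convention, including negative slices would let an
all-background predictor score highly. An untrained (randomly initialized)
model scores near 0; the pretrained-then-fine-tuned model recovers most of
the lesion area (Dice ≈ 0.5–0.86 across seeds). Problem sizes throughout
the tests (48–64 px phantoms, 2–4 block encoders) were chosen so the whole
suite runs in minutes on a single CPU core.

## Known limitations

* 2-D slice model; no use of 3-D context beyond scan-level evaluation.
* The autodiff engine favours clarity over speed; `vit_b` training is out
  of desk scope by design.
* The boundary-loss formulation and the Tversky variant are pinned choices
  among several published forms.
* DICOM support is a deliberately minimal Explicit-VR Little-Endian subset
  (the tags this pipeline needs), cross-checked against pydicom; it is not
  a general DICOM implementation.
* Phantom realism is limited as described above; conclusions about clinical
  data require the full-scale system and real annotations.
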