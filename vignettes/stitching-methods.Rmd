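---
title: "Stitchable hybrid CNN-transformer networks for OCT staging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitchable hybrid CNN-transformer networks for OCT staging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octstitch)
```

## The problem

Age-related macular degeneration (AMD) is staged on retinal OCT B-scans into
three phenotypes: *normal*, *drusen* (localized sub-retinal deposits that
elevate the retinal pigment epithelium, the hallmark of dry AMD) and *CNV*
(choroidal neovascularization, the wet-AMD lesion: hyperreflective
sub-retinal material with adjacent fluid). `octstitch` implements, natively
in R, the two ingredients of an architecture-search approach to this
classification task:

1. a family of **hybrid CNN-transformer backbones** in two sizes, *micro*
   and *tiny*, identical except for the depth of the third stage; and
2. **model stitching**: given two pre-trained "anchor" networks, a search
   space of candidate architectures is formed by running the smaller anchor
   up to block $n$, mapping its activations into the larger anchor at block
   $m$ through a per-position linear (1x1 convolution) *stitch layer*, and
   continuing to the larger anchor's classifier. The stitches are
   initialized in closed form by least squares and the whole space is then
   trained jointly by sampling one random candidate per iteration.

Everything runs on synthetic OCT-like images shipped with the package, so
the full pipeline is testable without any external dataset or GPU.

## The backbone

Both model sizes share a 4-convolution stem (3x3 kernels; channels
64-32-64-64; strides 2-1-1-2, total stride 4) and four stages. Each stage
begins with a patch embedding (stride-2 average pool, except stage 1, then a
1x1 projection with batch normalization) and stacks two block kinds:

* **ECB** (efficient convolutional block): multi-head convolutional
  attention (MHCA) followed by a locally-enhanced feed-forward network
  (LFFN), each wrapped in a residual connection. MHCA aggregates every
  spatial token with its 3x3 neighbourhood through per-head learnable
  weights — realized as a grouped 3x3 convolution with one group per head —
  then mixes heads with a 1x1 output projection.
* **LTB** (local transformer block): an efficient self-attention (ESA)
  module first, then MHCA on a complementary channel split, then the LFFN.
  ESA is standard multi-head scaled dot-product attention over the spatial
  tokens except that keys and values are computed from an average-pooled
  copy of the input with stride $s$ (stage-wise $s = 4, 2, 1$), reducing
  the token count by about $s^2$. At $s = 1$ the layer is exactly multi-head
  self-attention, which is one of the package's tested invariants.
* **LFFN**: 1x1 expansion, 3x3 depthwise convolution, hard-swish
  activations, a squeeze-excitation gate and a 1x1 projection, with a
  residual connection.

The stage layout is: stage 1 `[ECB96 x3]`, stage 2 `[ECB192 x3, LTB256]`,
stage 3 `[ECB384 x4, LTB512]` repeated once (micro) or twice (tiny), stage 4
`[ECB768 x2, LTB1024]`. The classifier is batch norm, global average pool
and a linear 3-class head. Path dropout (stochastic depth on the residual
branches, linearly scaled with depth) is 0.05 for micro and 0.1 for tiny.
With 224x224 input the stage resolutions are 56, 28, 14 and 7 pixels.

### Block-internal conventions and the parameter counts

The architecture table pins down channel widths, strides and repeats but not
the block internals. Those are exposed in `medvit_conventions()` and were
fixed once, from the conventional ranges of this block family, such that the
micro and tiny models reproduce the published sizes of this backbone pair —
24.50 and 31.14 million trainable parameters with a 3-class head:
LFFN expansion 3 in ECB and 2 in LTB, one attention head per 32 channels,
62.5% of LTB channels on the self-attention path (rounded to a multiple of
the head width), squeeze-excitation with inner width equal to the expansion
ratio, bias-free attention projections, batch-normalized pooled keys/values,
a batch norm after the MHCA projection, and biased convolutions. Since the
tiny model differs from micro only by one extra stage-3 group, the
difference of the two counts equals the analytic parameter sum of that
group; the test suite checks this identity layer by layer.

```{r params, eval = FALSE}
count_parameters(build_medvit(medvit_spec("micro"), seed = 1)) / 1e6 # 24.50
count_parameters(build_medvit(medvit_spec("tiny"), seed = 1)) / 1e6  # 31.14
```

## Stitching

**Enumeration.** Cut points are individual ECB/LTB blocks. A 1x1 stitch
cannot change spatial resolution, so only same-stage pairs are admitted.
For stages of equal depth the *paired* strategy slides a window of length 2
with step 1 over aligned positions, giving `(n, m = n + 1)` and $L - 1$
candidates for depth $L$. When the front stage is shallower (micro's stage 3
has 5 blocks, tiny's 10), the *unpaired* strategy assigns back positions to
front blocks by proportional buckets,
$n = \lfloor (j-1) \cdot L_a / L_b \rfloor + 1$, each assignment yielding
`(n, m = j + 1)` when `m` stays within the stage. Stage-wise candidate lists
are concatenated in depth order; because consecutive candidates are
near-duplicates, every second one (odd raw index) is pruned and survivors
re-indexed from 0. Both the raw and the pruned spaces, with their `(n, m)`
pairs, are written to the space manifest so any external configuration
numbering can be mapped onto ours.

**Initialization.** Each stitch is an affine map fitted to a mini-batch of
100 samples: with front activations $A$ and back activations $B$ flattened
to token-by-channel matrices, the weight minimizes the Frobenius residual
$\lVert A W - B \rVert$ via the normal-equations/QR closed form; a bias
column is appended, which strictly generalizes the linear fit at negligible
cost. Rank-deficient batches (possible at small image sizes where a cut has
fewer tokens than channels) fall back to the minimum-norm pseudo-inverse
solution with a warning. Raw block outputs are used, not post-normalization
activations. Tested invariants: a planted affine map is recovered to 1e-5,
the residual equals an independently computed normal-equations residual, no
random perturbation of the solution improves the fit, and stitching a model
to itself with an identity-initialized stitch reproduces the original
logits to 1e-5 at every cut.

**Training.** Per iteration one configuration is drawn uniformly at random
and one mini-batch is passed through that stitched path; focal loss
gradients update all parameters on the active path (a `freeze_anchors` mode
restricts updates to the stitch). The learning rate follows cosine annealing
from a base rate scaled linearly with batch size (reference batch 32) to
zero, without restarts. The stitching loss defaults to the same
inverse-class-frequency focal weighting as pre-training; with uniform
weights, briefly-trained mid-network configurations sit in a
majority-class basin on imbalanced data.

**Per-configuration normalization statistics.** The anchors' blocks use
batch normalization, and they are shared between configurations that feed
them different activation distributions — so no single set of running
statistics can serve every configuration at evaluation time (this tension
does not arise in layer-norm transformer stitching, which has no batch
statistics). `calibrate_stitched()` therefore re-estimates the running
statistics along one configuration's path before it is evaluated: a single
training-mode pass over the whole calibration set as one batch, with update
momentum 1 and stochastic depth disabled. Because the batch then *is* the
population, batch-statistic normalization inside the pass coincides with
the updated running-statistic normalization used at evaluation, making the
estimate exact and self-consistent in one pass (mini-batch recalibration,
by contrast, chases a moving fixed point layer by layer). The five-fold
driver snapshots and restores the shared statistics around each
configuration's evaluation.

## Training and evaluation protocol

* **Focal loss** $-\alpha_y (1 - p_y)^\gamma \log p_y$ counteracts the
  class imbalance of AMD datasets (normal-majority). Defaults: $\gamma = 2$
  and inverse-class-frequency $\alpha$, both configurable; at $\gamma = 0$
  with uniform weights the loss reduces exactly to cross-entropy.
* **Augmentation** (training only, in order): random affine with rotation
  (-20, 20) degrees, translation up to (0.05, 0.2) of the image size,
  shear (-10, 10) degrees, scale (0.8, 1.2); brightness/contrast/saturation
  jitter factors (0.8, 1.2); horizontal flip with probability 0.5; then
  normalization with per-dataset statistics (presets: mean 0.13 / sd 0.194
  and mean 0.19 / sd 0.215). Saturation jitter is a no-op on grayscale
  input but its random draw is kept so the stream layout matches the
  transform list.
* **Pre-training** (the anchor recipe): stratified 80/20 train/validation
  split, AdamW at 5e-5 decayed by 0.1 at epoch 50, 75 epochs, batch 32;
  after every epoch the macro one-vs-rest validation AUC is computed and
  the checkpoint is kept whenever the AUC is greater than *or equal to* the
  best so far, so ties favour the later epoch. The split is stratified by
  class with a fixed seed — necessary on imbalanced data so every class is
  present in validation.
* **Metrics**: accuracy, macro-averaged sensitivity and specificity, and
  macro one-vs-rest AUC; macro (unweighted per-class) averaging is the
  convention that keeps specificity well defined with three classes. Fold
  aggregation reports mean ± 1.96 sd/sqrt(n) over the five folds (normal
  approximation, matching the ±x.xxx magnitudes such aggregates are printed
  with; a t-quantile alternative is available).
* **Five-fold driver**: the target dataset is split at image level with a
  fixed seed (an optional patient-grouped splitter exists, since real OCT
  datasets are patient-structured, but image-level splitting is the
  default and is flagged in the results). Out-of-distribution mode
  pre-trains both anchors once on the source dataset and stitches per fold
  on the remaining 4/5 of the target; in-distribution mode re-pre-trains
  the anchors per fold on the remainder. Zero-shot evaluation applies a
  trained model to an entire target dataset with the target's
  normalization preset and no weight update.

## The synthetic data generator

`generate_image()` renders a geometric phantom of a B-scan: a dark
background, three to four smoothly curved horizontal bands (inner retina,
a bright surface band, and a brightest deep band standing in for the RPE)
over a dim decaying choroid, with multiplicative gamma-distributed speckle
(mean 1, default variance 0.05 — the standard multiplicative speckle model
for coherent imaging) applied last. Class morphology: *drusen* adds 2-6
localized upward bumps (heights 7-14%, widths 5-9% of the image side)
deforming the deep band; *CNV* adds one large irregular hyperreflective
lesion beneath the band with an adjacent dark fluid pocket. All geometry is
specified in fractions of the image side so the phantom renders at any
resolution; defaults were chosen once so that the classes remain separable
under speckle, and a hand-coded detector (bright-column area for CNV,
band-deformation energy for drusen) classifies 1,000 fresh images at over
95% accuracy — the generator's acceptance bar, enforced in the test suite.
Class proportions default to a normal-majority imbalance (50/25/25),
approximating the real datasets' imbalance pattern; they are a config
input, not a calibrated copy of any published distribution.

What passing tests on this phantom do **not** show: robustness to scanner
artefacts, patient-level correlation, shadowing and optical effects, or the
fine-grained texture that makes real drusen/normal discrimination hard.
The phantom demonstrates that the machinery — blocks, gradients, stitching,
search, evaluation — is correct, not that the printed real-data accuracies
transfer.

## Numerical choices and desk-scale problem sizes

* All forward/backward passes are hand-written in R on a token-by-channel
  matrix layout; convolutions use im2col with memoized index maps; every
  layer's backward pass is verified against central finite differences.
* Batch normalization uses eps 1e-5 and momentum 0.1 (biased batch
  variance in the normalizer, unbiased in the running estimate).
* AdamW uses betas (0.9, 0.999), eps 1e-8 and decoupled weight decay 0.01
  on all parameters.
* The least-squares initialization uses QR; the rank-deficient branch
  switches to the SVD pseudo-inverse (tolerance
  `max(dim) * eps * d_max`).
* The `reduced_micro` / `reduced_tiny` presets divide all channel widths by
  8, set all within-group repeats to 1 (keeping the stage-3 group repeat
  that distinguishes the two sizes), and use 4-channel heads. They are the
  package's desk-scale study size: the end-to-end acceptance study runs
  600 synthetic 32x32 B-scans per dataset, 5 pre-training epochs per
  anchor, 200 stitching iterations and five folds. At this scale and
  from-scratch initialization the full-study learning rate of 5e-5 would
  barely move the weights, so the toy protocol uses 1e-2 without
  augmentation; the full-scale defaults remain the package defaults.
* Determinism: model construction, pre-training, stitch initialization and
  stitching are bitwise reproducible given their seeds; all randomness
  flows through R's RNG.

## Known limitations

* CPU-only and R-native: full-size models build and count correctly (that
  is how the 24.50M/31.14M figures are produced) and run forward at
  224x224, but full-scale training is out of reach here by design.
* Only two anchors, one direction (smaller into larger), no
  teacher-distillation variant of stitching.
* The unpruned/pruned candidate numbering is logged rather than guaranteed
  to match any external convention, since published configuration ids
  cannot be reconstructed from their descriptions alone.
* The 4-class variant of the source task (a fourth macular phenotype in
  some datasets) is not modelled; heads are 3-class throughout.
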