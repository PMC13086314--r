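---
title: "Adaptive Window Pyramid Fusion: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Window Pyramid Fusion: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fine-grained classification of edible mushroom species is hard for three
reasons: the discriminative cues (cap texture, gill pattern, margin shape)
are small relative to the fruiting body; inter-class shape variation is
large while inter-class colour differences can be subtle; and realistic
datasets are small and heavily imbalanced (here, one class has an order of
magnitude fewer images than another). Deep convolutional stacks progressively
downsample and can discard exactly the fine texture that separates, say, a
brown *Agaricus bisporus* from *Lentinula edodes*.

`awpfnet` implements a classifier built around this failure mode. The
architecture keeps only the early, high-resolution part of an 18-layer
residual network and compensates for the lost depth with an attention-based
multi-scale fusion module.

## Architecture

**Truncated backbone.** The stem (7×7 conv, stride 2, + 3×3 max-pool) and
the first two residual stages (64- and 128-channel) downsample the input by
8. A 1×1 convolutional adapter maps the 128 channels to 256 and yields the
base feature `F0` (28×28 for a 224×224 input). Stages 3–4 of the original
network are deliberately removed: they would downsample further and their
parameters dominate the budget. The adapter is followed by batch-norm and
ReLU by default (`adapter_norm`); the bare 1×1 conv is available by flag.

**Downsampling pyramid.** `F1` and `F2` are produced from `F0` by 3×3
stride-2 convolutions (+BN+ReLU), halving the side each time
(28 → 14 → 7 at full resolution).

**Dynamic Swin Window (DSW) enhancement.** Each pyramid level is refined by
a stack (default depth 2) of pre-norm transformer blocks that compute
self-attention inside non-overlapping M×M windows,

$$\mathrm{Attention}(Q,K,V) = \mathrm{Softmax}\!\left(\frac{QK^\top}{\sqrt{d_k}} + B\right) V,$$

where \(B\) is a learned relative-position bias indexed by in-window offset.
The window size adapts to the level: 7×7 on the shallow level 1, 5×5 on the
deeper level 2 ("mix" strategy); fixed 5×5 or 7×7 everywhere are available
as ablation configurations. Odd-indexed blocks shift the partition
cyclically by `min(3, ⌊H/2⌋, ⌊W/2⌋)` so neighbouring windows exchange
information; even-indexed blocks are unshifted. Maps whose side is not a
multiple of M are zero-padded bottom-right and the padded keys are masked
out of the softmax, as are key/query pairs separated by a wrap-around seam
of the cyclic shift. A query whose keys are all masked attends to itself
(this cannot occur for real positions under the partition used here, but
the convention keeps the operation total).

**Bottom-up fusion.** The enhanced `F2` is bilinearly upsampled to the size
of `F1` and added (`F1_enh = F1 + U1`); the enhanced `F1_enh` is upsampled
to `F0` and added (`F_AWPF = F0 + U0`). Fusion is plain element-wise
addition — no learned gating. Global average pooling and a linear layer
produce the logits; the cross-entropy loss applies the softmax.

### Fusion-order choice

Two orderings of "enhance" and "upsample+add" are conceivable: running the
window attention at each level's native resolution and then upsampling the
result, or upsampling/adding first and enhancing the fused map. We adopt
the first as canonical: it matches the explicit forward procedure the
architecture is defined by, it keeps the attention windows aligned with the
level whose statistics they were sized for (7×7 windows on 14×14 maps, 5×5
on 7×7), and it is cheaper. The alternative order remains available via
`fuse_before_dsw = TRUE` for comparison.

### Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `window_strategy` | `"mix"` | 7×7 at level 1, 5×5 at level 2; `fixed5`/`fixed7` for ablations |
| `dsw_depth` | 2 | blocks per stack; depth ≥ 2 is needed for any shifted block to occur, since block 0 is always unshifted |
| `num_heads` | 8 | head dim 32 at 256 channels; common shifted-window practice |
| `mlp_ratio` | 4 | feed-forward expansion; the feed-forward sublayer can be removed (`use_mlp = FALSE`) |
| `shift_cap` | 3 | upper bound of the cyclic shift |
| `cross_scale` | `TRUE` | additive skips from shallower levels; `FALSE` is the cross-scale ablation |
| `lr` / `batch_size` / `epochs` | 0.001 / 32 / 50 | the study protocol (AdamW) |
| `weight_decay` | 0.01 | decoupled; applied to weight tensors only, not biases/norms |

The head count, MLP presence and pre-norm layout are not dictated by the
architecture's description; the defaults follow standard shifted-window
transformer practice and are all config-exposed. The default model has
about 5.06 M trainable parameters — comfortably inside the stated <30 M
budget for this architecture family.

## Numerical engine

No tensor-autodiff framework is assumed: the package carries its own
reverse-mode automatic differentiation over dense R arrays (environments as
graph nodes, a per-forward tape, GEMM-based convolution via `im2col`
compiled in C++). Gradients of every layer type are verified against
central finite differences in the test suite's development harness, and the
windowed-attention forward is tested against an independent dense oracle.
Bilinear resampling uses separable interpolation matrices without corner
alignment; its adjoint is the transposed matrices. Batch-norm uses batch
statistics in training (running statistics updated with momentum 0.1,
unbiased variance) and running statistics at inference, which makes
inference deterministic.

Numerical conventions worth knowing:

- masked attention logits use an additive −10⁹, and a fully-masked row
  falls back to a one-hot on itself rather than NaN;
- softmax subtracts the row maximum before exponentiation;
- `accuracy`/macro metrics on an empty matrix raise an error rather than
  returning NaN;
- classes never predicted contribute precision 0 (and classes without true
  samples recall 0) to the macro means — degenerate predictors on the
  rare "Mix" class are penalised, not silently dropped;
- on very small pyramid maps (side ≤ 2) a shifted partition can leave a
  position alone in its attention neighbourhood; the softmax over a single
  key is constant, so the relative-position bias receives a structurally
  zero gradient there. This is expected geometry, not a dead branch — at
  the study's input resolution every level has multi-key neighbourhoods.

## The synthetic data generator

Real mushroom photographs cannot ship with the package, so the `data`
module renders a procedural stand-in: each class is a parametric silhouette
(cap ellipse + stipe rectangle) with a class-specific palette and texture —
pink gill stripes (*Agaricus bisporus*), pale spots on red-brown
(*Boletus*), high-frequency white spines (*Hericium erinaceus*), pale
cracks on dark brown (*Lentinula edodes*), a dominant pale stipe
(*Pleurotus eryngii*), yellow folded ridges (*Tremella*) — over cluttered
backgrounds, with seeded jitter in pose, scale, illumination and palette.
The "Mix" class draws one of the other six renderers uniformly per image.
The default composition reproduces the study dataset exactly: 1,713
training and 722 validation images over 7 classes, including the 14/10-image
"Mix" class, so the class imbalance that motivates macro-metric emphasis is
present in every test.

Every image is a pure function of `(spec, seed)`; identical inputs yield
byte-identical PNG trees. Palettes are spaced so that a multinomial linear
probe on per-image mean colour reaches ≥90 % validation accuracy — this
guarantee is what makes the downstream training tests meaningful: if the
full model cannot beat a 3-feature linear probe, something is wrong with
the model, not the data.

What the generator does *not* emulate: photographic texture statistics,
occlusion, multiple instances per image, viewpoint-dependent shading, or
label noise. Passing tests therefore demonstrate that the implementation
optimises and classifies correctly on separable image data — they say
nothing about accuracy on real mushroom photographs, which is why the
study's headline accuracy values are out of scope here.

## Desk-scale study conditions

The full protocol (224×224 inputs, 50 epochs, ten models, five seeds) is a
GPU-scale experiment. The package's own verification runs are sized for a
single CPU and are fixed once:

- **Overfit sanity**: one batch of 8 random 32×32 images, 60 AdamW steps,
  training loss must fall below 0.1 (it reaches ~10⁻⁶).
- **End-to-end training**: the default composition scaled by 0.5
  (857 train / 361 validation images) rendered at 64×64, 5 epochs with the
  protocol hyperparameters (batch 32, AdamW, lr 0.001), seed 0; validation
  accuracy must reach ≥95 %. The scale factor preserves relative class
  imbalance and is the largest reduction-free-enough count that keeps the
  run inside a single-CPU budget; 64×64 keeps the full architecture (all
  three pyramid levels, both window sizes, shifted blocks) active. At a
  quarter of the composition the run is faster but optimisation becomes
  visibly less stable (fewer steps per epoch), which is itself informative
  about the method's data appetite.

## Known limitations

- Training is CPU-bound and single-threaded apart from BLAS; the package is
  a faithful, testable reference implementation, not a speed-competitive
  trainer.
- `pretrained = TRUE` is declined rather than emulated: no weight source is
  bundled, and whether the original model used pretraining is unstated, so
  neither mode is claimed to reproduce it.
- The PR-curve construction (one-vs-rest, thresholds at the distinct
  scores, rectangle-rule area) is one of several common conventions; the
  worked examples in the tests pin the implemented one down.
- JPEG decoding requires the optional EBImage package; PNG is native.
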