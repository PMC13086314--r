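# awpfnet

Fine-grained image classification of edible mushroom species with
**AWPF-ResNet18**: a truncated residual backbone augmented by an
**Adaptive Window Pyramid Fusion** (AWPF) module built from **Dynamic Swin
Window** (DSW) blocks — shifted-window self-attention whose window size
adapts to the pyramid level.

## Who this is for

Researchers working on fine-grained, class-imbalanced biological image
classification who need a fully inspectable, dependency-light reference
implementation of window-attention pyramid fusion: every component — the
truncated backbone, the windowed attention with its shift/padding masks,
the reverse-mode autodiff engine it trains with, the macro metrics, and a
synthetic data generator that makes the whole pipeline testable without any
external images — is plain R (plus two small C++ kernels) and unit-tested
against independent oracles.

## The model

An input image `X` (224×224 RGB) flows through:

1. **Truncated backbone** — 7×7 stride-2 conv + 3×3 max-pool, then the
   first two residual stages only, then a 1×1 adapter to 256 channels:
   `F0 = Adapter(ResNet18_Backbone(X))`, 28×28×256.
2. **Pyramid** — `F_{i+1} = conv3x3(F_i, stride 2, pad 1)` for i = 0, 1
   (each + BN + ReLU), giving 14×14 and 7×7 levels.
3. **DSW enhancement + bottom-up fusion** — each level runs a stack of
   pre-norm transformer blocks with windowed attention

   `Attention(Q, K, V) = Softmax(Q Kᵀ / √d_k + B) V`

   inside M×M windows (M = 7 at level 1, M = 5 at level 2), alternating
   unshifted and cyclically shifted partitions with masked seams; then
   `U1 = Upsample(DSW(F2))`, `F1_enh = F1 + U1`,
   `U0 = Upsample(DSW(F1_enh))`, `F_AWPF = F0 + U0`.
4. **Head** — global average pooling + linear map to K classes.

Evaluation uses imbalance-aware macro metrics: accuracy, and the means over
classes of per-class precision, recall, and F1 (MP/MR/MF), with macro
recall emphasised for model selection.

## Worked example

```r
library(awpfnet)

# 1. a small synthetic dataset (full default: default_mushroom_spec())
spec <- default_mushroom_spec(image_size = c(64, 64), seed = 0, scale = 0.5)
root <- file.path(tempdir(), "mushrooms")
set <- generate_synthetic_dataset(spec, root)
nrow(set)
#> [1] 1218

# 2. train for five epochs with the protocol hyperparameters
fit <- train(train_config(image_size = 64, epochs = 5, seed = 0), root)
tidy(fit)
#> # A tibble: 5 × 6
#>   epoch train_loss val_acc val_mp val_mr val_mf
#>   <int>      <dbl>   <dbl>  <dbl>  <dbl>  <dbl>
#> 1     1     0.335    0.598  0.533  0.571  0.459
#> 2     2     0.539    0.964  0.817  0.830  0.823
#> 3     3     0.113    0.981  0.837  0.853  0.845
#> 4     4     0.0879   0.986  0.842  0.857  0.849
#> 5     5     0.0696   0.986  0.842  0.857  0.849
```

Validation accuracy passes 95 % by epoch 2; macro recall sits lower because
the deliberately tiny, inherently ambiguous "Mix" class (images drawn from
the other six classes' renderers) drags the per-class mean down — exactly
the imbalance effect the macro metrics are there to expose. The best
checkpoint is selected by validation macro recall.

```r
# 3. model size and structure
model <- awpf_resnet18(num_classes = 7)
count_parameters(model)
#> [1] 5061863            # ~5.06M, well under the 30M budget
count_parameters(baseline_resnet18(1000))
#> [1] 11689512           # the canonical untruncated baseline

# 4. evaluation artifacts and explanation
ev <- evaluate(fit$model, root, seeds = 0, image_size = 64)
ev$summary                       # mean +/- SD per metric
autoplot(ev$reports[[1]]$confusion)   # normalised confusion heatmap
img <- png::readPNG(set$path[1])          # already 64 x 64 x 3
cam <- grad_cam(fit$model, img, class_index = 0)   # [0,1] heatmap, (64, 64)
```

A command-line interface wrapping the same functions is installed at
`system.file("cli", "awpfnet.R", package = "awpfnet")`, with subcommands
`generate-data`, `train`, `eval`, `explain` and `params`.

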