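# Adaptive Window Pyramid Fusion: convolutional downsampling pathway,
# bottom-up DSW-enhanced fusion, and the global-average-pool + linear
# classification head.

#' Assemble the full AWPF classification model
#'
#' Builds the truncated residual backbone with its 1x1 adapter, the two
#' stride-2 pyramid convolutions, one DSW block stack per pyramid level
#' (window size chosen by the window strategy), and the classification head.
#'
#' @param num_classes Number of output classes (at least 2; default 7).
#' @param window_strategy `"mix"` (7x7 at level 1, 5x5 at level 2),
#'   `"fixed5"`, or `"fixed7"`.
#' @param cross_scale Keep the additive skip connections from the shallower
#'   pyramid levels during fusion (default TRUE). Turning this off is the
#'   cross-scale ablation: only the DSW chain output is returned.
#' @param dsw_depth Blocks per DSW stack (default 2: regular + shifted).
#' @param num_heads Attention heads (default 8, head dim 32 at 256 channels).
#' @param mlp_ratio Feed-forward expansion ratio (default 4).
#' @param use_mlp Include the feed-forward sublayer in DSW blocks.
#' @param shift_cap Maximum cyclic shift for shifted blocks (default 3).
#' @param fuse_before_dsw Apply DSW after adding the upsampled deeper
#'   feature instead of before upsampling (alternative fusion order, off by
#'   default; see the methods vignette).
#' @param adapter_channels Pyramid channel width (default 256).
#' @param seed Seed for weight initialisation.
#' @return An `awpf_model` object.
#' @export
awpf_resnet18 <- function(num_classes = 7L,
                          window_strategy = c("mix", "fixed5", "fixed7"),
                          cross_scale = TRUE,
                          dsw_depth = 2L,
                          num_heads = 8L,
                          mlp_ratio = 4,
                          use_mlp = TRUE,
                          shift_cap = 3L,
                          fuse_before_dsw = FALSE,
                          adapter_channels = 256L,
                          seed = 0L) {
  window_strategy <- match.arg(window_strategy)
  if (num_classes < 2) stop("num_classes must be at least 2")
  if (dsw_depth < 1) stop("dsw_depth must be at least 1")
  cfg <- list(num_classes = as.integer(num_classes),
              window_strategy = window_strategy,
              cross_scale = isTRUE(cross_scale),
              dsw_depth = as.integer(dsw_depth),
              num_heads = as.integer(num_heads),
              mlp_ratio = mlp_ratio,
              use_mlp = isTRUE(use_mlp),
              shift_cap = as.integer(shift_cap),
              fuse_before_dsw = isTRUE(fuse_before_dsw),
              adapter_channels = as.integer(adapter_channels),
              seed = as.integer(seed))
  backbone <- awpf_backbone(backbone_config(adapter_channels = adapter_channels,
                                            seed = seed))
  with_seed(seed + 1L, {
    C <- as.integer(adapter_channels)
    pyramid <- list(conv1 = new_conv(C, C, 3L), bn1 = new_bn(C),
                    conv2 = new_conv(C, C, 3L), bn2 = new_bn(C))
    dsw <- list(
      level1 = make_dsw_params(C, select_window_size(1L, window_strategy),
                               dsw_depth, num_heads, mlp_ratio, use_mlp),
      level2 = make_dsw_params(C, select_window_size(2L, window_strategy),
                               dsw_depth, num_heads, mlp_ratio, use_mlp))
    head <- new_linear(C, as.integer(num_classes))
    structure(list(backbone = backbone, pyramid = pyramid, dsw = dsw,
                   head = head, cfg = cfg),
              class = "awpf_model")
  })
}

#' @export
print.awpf_model <- function(x, ...) {
  cat("<awpf_model> ", x$cfg$num_classes, "-class AWPF-ResNet18\n", sep = "")
  cat("  window strategy:", x$cfg$window_strategy,
      "| cross-scale:", x$cfg$cross_scale,
      "| DSW depth:", x$cfg$dsw_depth, "\n")
  cat("  trainable parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

ag_pyramid_conv <- function(x, conv, bn) {
  ag_relu(ag_batchnorm(ag_conv2d(x, conv$w, stride = 2, pad = 1),
                       bn$g, bn$b, bn$state))
}

ag_build_pyramid <- function(f0, model) {
  d <- dim(f0$value)
  if (d[3] < 4 || d[4] < 4)
    stop("base feature side must be at least 4 (got ", d[3], "x", d[4],
         "); the pyramid would degenerate below 1x1")
  f1 <- ag_pyramid_conv(f0, model$pyramid$conv1, model$pyramid$bn1)
  f2 <- ag_pyramid_conv(f1, model$pyramid$conv2, model$pyramid$bn2)
  list(f0 = f0, f1 = f1, f2 = f2)
}

#' Build the downsampling feature pyramid
#'
#' Derives levels F1 and F2 from the base feature F0 by stride-2 3x3
#' convolutions, each followed by batch-norm and ReLU, halving the spatial
#' side at each level (`side_out = floor((side_in + 2 - 3) / 2) + 1`).
#'
#' @param f0 A level-0 [feature_map()] (e.g. from [extract_base_features()]).
#' @param model An `awpf_model` providing the pyramid convolution weights.
#' @return A `pyramid_levels` list with feature maps `f0`, `f1`, `f2`.
#' @export
build_pyramid <- function(f0, model) {
  stopifnot(inherits(model, "awpf_model"))
  if (fm_level(f0) != 0L) stop("build_pyramid expects a level-0 feature map")
  p <- ag_build_pyramid(ag_constant(fm_data(f0)), model)
  structure(list(f0 = feature_map(p$f0$value, 0L),
                 f1 = feature_map(p$f1$value, 1L),
                 f2 = feature_map(p$f2$value, 2L)),
            class = "pyramid_levels")
}

ag_fuse <- function(pyr, model, dsw_fn = NULL) {
  cfg <- model$cfg
  d1 <- dim(pyr$f1$value)[3:4]
  d0 <- dim(pyr$f0$value)[3:4]
  dsw_fn <- dsw_fn %||% function(x, target_hw, level) {
    params <- if (level == 2L) model$dsw$level2 else model$dsw$level1
    ag_dsw_apply(x, target_hw, params, cfg$shift_cap)
  }
  if (cfg$fuse_before_dsw) {
    # Alternative order: upsample the deeper feature first, add, then run
    # DSW on the fused map at the shallower resolution.
    u1 <- dsw_fn(ag_bilinear_resize(pyr$f2, d1[1], d1[2]), d1, 2L)
    f1e <- if (cfg$cross_scale) ag_add(pyr$f1, u1) else u1
    u0 <- dsw_fn(ag_bilinear_resize(f1e, d0[1], d0[2]), d0, 1L)
  } else {
    # Canonical order: DSW at native resolution, upsample, then add.
    u1 <- dsw_fn(pyr$f2, d1, 2L)
    f1e <- if (cfg$cross_scale) ag_add(pyr$f1, u1) else u1
    u0 <- dsw_fn(f1e, d0, 1L)
  }
  if (cfg$cross_scale) ag_add(pyr$f0, u0) else u0
}

#' Fuse pyramid levels bottom-up through DSW enhancement
#'
#' The deepest level F2 is DSW-enhanced and upsampled to the size of F1,
#' added to it (`F1_enh = F1 + U1`), then the enhanced F1 is DSW-enhanced and
#' upsampled to the size of F0 and added (`F_AWPF = F0 + U0`). With
#' `cross_scale = FALSE` the additive skip terms are omitted and only the
#' DSW chain output is returned.
#'
#' @param pyramid A `pyramid_levels` list from [build_pyramid()].
#' @param model An `awpf_model`.
#' @param dsw_fn Optional override of the DSW stage, a
#'   `function(node, target_hw, level)` returning a node; used for
#'   dependency-injection in tests.
#' @return A [feature_map()] with the spatial size of F0.
#' @export
fuse <- function(pyramid, model, dsw_fn = NULL) {
  stopifnot(inherits(model, "awpf_model"))
  pyr <- list(f0 = ag_constant(fm_data(pyramid$f0)),
              f1 = ag_constant(fm_data(pyramid$f1)),
              f2 = ag_constant(fm_data(pyramid$f2)))
  out <- ag_fuse(pyr, model, dsw_fn)
  d0 <- dim(pyr$f0$value)[3:4]
  if (!identical(dim(out$value)[3:4], d0))
    stop("internal contract violation: fused map size ",
         paste(dim(out$value)[3:4], collapse = "x"),
         " does not match F0 size ", paste(d0, collapse = "x"))
  feature_map(out$value, 0L)
}

#' Classification head: global average pooling + linear map
#'
#' @param f A [feature_map()] (typically the fused AWPF output).
#' @param model An `awpf_model` providing the head weights.
#' @return A `(B, num_classes)` logit matrix (no softmax; the loss handles
#'   normalisation).
#' @export
classify <- function(f, model) {
  stopifnot(inherits(model, "awpf_model"))
  x <- if (inherits(f, "feature_map")) fm_data(f) else f
  if (dim(x)[2] != nrow(model$head$w$value))
    stop("feature channels (", dim(x)[2], ") do not match head weights (",
         nrow(model$head$w$value), ")")
  ag_linear(ag_gap(ag_constant(x)), model$head$w, model$head$b)$value
}

# Full forward pass on nodes; returns intermediate nodes for Grad-CAM.
ag_awpf_forward <- function(x, model) {
  f0 <- ag_backbone_forward(x, model$backbone)
  pyr <- ag_build_pyramid(f0, model)
  fused <- ag_fuse(pyr, model)
  logits <- ag_linear(ag_gap(fused), model$head$w, model$head$b)
  list(logits = logits, f0 = f0, fused = fused, pyramid = pyr)
}

#' Predict with an AWPF model
#'
#' Composes feature extraction, pyramid construction, DSW fusion and the
#' classification head. Deterministic in inference mode (batch-norm uses
#' running statistics).
#'
#' @param object An `awpf_model`.
#' @param images `(B, 3, H, W)` array, spatial sides multiples of 8.
#' @param type `"logits"` (default), `"prob"` (softmax scores), or
#'   `"class"` (1-based predicted class index).
#' @param ... Unused.
#' @return Matrix of logits or probabilities, or an integer vector.
#' @export
predict.awpf_model <- function(object, images,
                               type = c("logits", "prob", "class"), ...) {
  type <- match.arg(type)
  x <- check_image_batch(images)
  ag_set_training(FALSE)
  logits <- ag_awpf_forward(ag_constant(x), object)$logits$value
  switch(type,
         logits = logits,
         prob = softmax_rows(logits),
         class = max.col(logits, ties.method = "first"))
}
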