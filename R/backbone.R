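# Truncated residual backbone: 7x7 stem + max-pool, the first two residual
# stages of an 18-layer residual network, and a 1x1 channel adapter that
# produces the base pyramid feature F0. The untruncated 4-stage classifier
# is kept as the ablation baseline.

#' Backbone configuration
#'
#' @param adapter_channels Channels produced by the 1x1 adapter (default 256).
#' @param truncate_after_stage Keep the first 2 residual stages (default) or
#'   all 4 (untruncated variant).
#' @param pretrained Load externally supplied pretrained weights. Off by
#'   default: weights are He-initialised from the seed so builds are fully
#'   reproducible offline.
#' @param adapter_norm Follow the adapter conv with batch-norm + ReLU
#'   (default TRUE).
#' @param seed Integer seed for weight initialisation.
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(adapter_channels = 256L, truncate_after_stage = 2L,
                            pretrained = FALSE, adapter_norm = TRUE,
                            seed = 0L) {
  stopifnot(adapter_channels > 0)
  if (!truncate_after_stage %in% c(2L, 4L))
    stop("truncate_after_stage must be 2 (truncated) or 4 (full backbone)")
  if (isTRUE(pretrained))
    stop("no pretrained weight source is bundled; supply weights via ",
         "load_checkpoint() instead")
  structure(list(adapter_channels = as.integer(adapter_channels),
                 truncate_after_stage = as.integer(truncate_after_stage),
                 pretrained = FALSE,
                 adapter_norm = isTRUE(adapter_norm),
                 seed = as.integer(seed)),
            class = "backbone_config")
}

new_basic_block <- function(cin, cout, stride = 1L) {
  b <- list(conv1 = new_conv(cin, cout, 3L),
            bn1 = new_bn(cout),
            conv2 = new_conv(cout, cout, 3L),
            bn2 = new_bn(cout),
            stride = stride)
  if (stride != 1L || cin != cout) {
    b$down_conv <- new_conv(cin, cout, 1L)
    b$down_bn <- new_bn(cout)
  }
  b
}

new_stage <- function(cin, cout, stride) {
  list(block1 = new_basic_block(cin, cout, stride),
       block2 = new_basic_block(cout, cout, 1L))
}

ag_basic_block <- function(x, b) {
  out <- ag_relu(ag_batchnorm(ag_conv2d(x, b$conv1$w, stride = b$stride, pad = 1),
                              b$bn1$g, b$bn1$b, b$bn1$state))
  out <- ag_batchnorm(ag_conv2d(out, b$conv2$w, stride = 1, pad = 1),
                      b$bn2$g, b$bn2$b, b$bn2$state)
  short <- if (!is.null(b$down_conv)) {
    ag_batchnorm(ag_conv2d(x, b$down_conv$w, stride = b$stride, pad = 0),
                 b$down_bn$g, b$down_bn$b, b$down_bn$state)
  } else x
  ag_relu(ag_add(out, short))
}

ag_stage <- function(x, st) ag_basic_block(ag_basic_block(x, st$block1), st$block2)

new_stem <- function() {
  list(conv = new_conv(3L, 64L, 7L), bn = new_bn(64L))
}

ag_stem <- function(x, stem) {
  out <- ag_relu(ag_batchnorm(ag_conv2d(x, stem$conv$w, stride = 2, pad = 3),
                              stem$bn$g, stem$bn$b, stem$bn$state))
  ag_maxpool(out, k = 3, stride = 2, pad = 1)
}

#' Build a truncated residual backbone
#'
#' Constructs the stem, the retained residual stages, and the 1x1 channel
#' adapter. With the default truncation after stage 2 the backbone
#' downsamples by a factor of 8 (stem conv x2, max-pool x2, stage-2 x2), so a
#' 224x224 input yields a 28x28 base feature.
#'
#' @param cfg A [backbone_config()].
#' @return An `awpf_backbone` object.
#' @export
awpf_backbone <- function(cfg = backbone_config()) {
  stopifnot(inherits(cfg, "backbone_config"))
  with_seed(cfg$seed, {
    stages <- list(stage1 = new_stage(64L, 64L, 1L),
                   stage2 = new_stage(64L, 128L, 2L))
    last <- 128L
    if (cfg$truncate_after_stage == 4L) {
      stages$stage3 <- new_stage(128L, 256L, 2L)
      stages$stage4 <- new_stage(256L, 512L, 2L)
      last <- 512L
    }
    params <- list(stem = new_stem(), stages = stages,
                   adapter = new_conv(last, cfg$adapter_channels, 1L,
                                      bias = !cfg$adapter_norm))
    if (cfg$adapter_norm) params$adapter_bn <- new_bn(cfg$adapter_channels)
    structure(list(params = params, cfg = cfg), class = "awpf_backbone")
  })
}

check_image_batch <- function(x) {
  if (inherits(x, "feature_map")) x <- fm_data(x)
  d <- dim(x)
  if (is.null(d) || length(d) != 4)
    stop("expected a 4-axis (batch, channel, height, width) image array")
  if (d[2] != 3)
    stop("channel axis (axis 2) must have size 3, got ", d[2])
  if (d[3] < 32 || d[4] < 32)
    stop("spatial side must be at least 32 (got ", d[3], "x", d[4],
         "); smaller inputs collapse under pooling")
  x
}

ag_backbone_forward <- function(x, bb) {
  p <- bb$params
  out <- ag_stem(x, p$stem)
  for (st in p$stages) out <- ag_stage(out, st)
  out <- if (is.null(p$adapter$b)) ag_conv2d(out, p$adapter$w)
         else ag_conv2d(out, p$adapter$w, p$adapter$b)
  if (!is.null(p$adapter_bn))
    out <- ag_relu(ag_batchnorm(out, p$adapter_bn$g, p$adapter_bn$b,
                                p$adapter_bn$state))
  out
}

#' Extract the base pyramid feature F0
#'
#' Runs an image batch through the stem, the retained residual stages and
#' the channel adapter. The output spatial side is the input side divided by
#' 8 under the default truncation (32 for the untruncated variant).
#'
#' @param images `(B, 3, H, W)` array with intensities in `[0, 1]`.
#' @param backbone An `awpf_backbone`, an `awpf_model`, or a
#'   [backbone_config()] (a seeded backbone is then built on the fly).
#' @return A [feature_map()] at level 0 with `adapter_channels` channels.
#' @export
#' @examples
#' bb <- awpf_backbone(backbone_config(seed = 1))
#' f0 <- extract_base_features(array(runif(2 * 3 * 64 * 64), c(2, 3, 64, 64)), bb)
#' dim(f0)  # 2 256 8 8
extract_base_features <- function(images, backbone = backbone_config()) {
  if (inherits(backbone, "backbone_config")) backbone <- awpf_backbone(backbone)
  if (inherits(backbone, "awpf_model")) backbone <- backbone$backbone
  stopifnot(inherits(backbone, "awpf_backbone"))
  x <- check_image_batch(images)
  out <- ag_backbone_forward(ag_constant(x), backbone)
  feature_map(out$value, 0L)
}

#' Untruncated 18-layer residual baseline classifier
#'
#' The canonical 4-stage architecture (stem, stages of width 64/128/256/512,
#' global average pooling, linear head), used as the ablation baseline. With
#' a 1000-class head it has 11,689,512 trainable parameters.
#'
#' @param num_classes Number of output classes (at least 2).
#' @param seed Seed for weight initialisation.
#' @return A `resnet18` model object.
#' @export
baseline_resnet18 <- function(num_classes, seed = 0L) {
  if (num_classes < 2) stop("num_classes must be at least 2")
  with_seed(seed, {
    params <- list(stem = new_stem(),
                   stages = list(stage1 = new_stage(64L, 64L, 1L),
                                 stage2 = new_stage(64L, 128L, 2L),
                                 stage3 = new_stage(128L, 256L, 2L),
                                 stage4 = new_stage(256L, 512L, 2L)),
                   fc = new_linear(512L, as.integer(num_classes)))
    structure(list(params = params, num_classes = as.integer(num_classes)),
              class = "resnet18")
  })
}

ag_resnet18_forward <- function(x, model) {
  p <- model$params
  out <- ag_stem(x, p$stem)
  for (st in p$stages) out <- ag_stage(out, st)
  ag_linear(ag_gap(out), p$fc$w, p$fc$b)
}

#' Predict with the baseline residual classifier
#'
#' @param object A `resnet18` model.
#' @param images `(B, 3, H, W)` image array.
#' @param ... Unused.
#' @return A `(B, num_classes)` logit matrix.
#' @export
predict.resnet18 <- function(object, images, ...) {
  x <- check_image_batch(images)
  ag_resnet18_forward(ag_constant(x), object)$value
}

#' Count trainable parameters
#'
#' Sums the element counts of every trainable weight array in a model
#' (convolution and linear weights, normalisation affine parameters,
#' attention projections and relative-position bias tables). Batch-norm
#' running statistics are buffers, not parameters, and are excluded.
#'
#' @param model An `awpf_model`, `awpf_backbone`, `resnet18`, or any nested
#'   list of parameter nodes.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  ps <- flatten_params(model)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}
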