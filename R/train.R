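# Training and evaluation: AdamW optimisation of the cross-entropy loss,
# per-epoch macro metrics, best-by-validation-macro-recall checkpointing,
# replicate aggregation, and Grad-CAM explanations.

#' Training configuration
#'
#' Defaults follow the study protocol: 224x224 inputs, batch size 32,
#' learning rate 0.001, AdamW, 50 epochs. Weight decay (unstated there)
#' defaults to 0.01 and is applied to weight matrices only, not to biases or
#' normalisation parameters.
#'
#' @param image_size Input side length (images are resized to a square).
#' @param batch_size Minibatch size.
#' @param lr Learning rate (fixed; no schedule).
#' @param optimizer Only `"adamw"` is provided.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param epochs Number of epochs (at least 1).
#' @param seed Seed for init, shuffling and any stochastic source.
#' @param num_classes Classifier width; inferred from the data if NULL.
#' @param window_strategy,cross_scale,dsw_depth,num_heads Ablation flags
#'   forwarded to [awpf_resnet18()].
#' @param select_by Checkpoint selection criterion: `"mr"` (validation
#'   macro recall, default), `"acc"`, `"mp"` or `"mf"`.
#' @param checkpoint Optional path to write the best checkpoint to.
#' @return A `train_config` list.
#' @export
train_config <- function(image_size = 224L, batch_size = 32L, lr = 0.001,
                         optimizer = "adamw", weight_decay = 0.01,
                         epochs = 50L, seed = 0L, num_classes = NULL,
                         window_strategy = "mix", cross_scale = TRUE,
                         dsw_depth = 2L, num_heads = 8L,
                         select_by = c("mr", "acc", "mp", "mf"),
                         checkpoint = NULL) {
  if (epochs < 1) stop("epochs must be at least 1")
  if (batch_size < 1 || lr <= 0 || weight_decay < 0 || image_size < 32)
    stop("hyperparameters must be positive (and image_size >= 32)")
  if (!identical(optimizer, "adamw")) stop("only the adamw optimizer is provided")
  structure(list(image_size = as.integer(image_size),
                 batch_size = as.integer(batch_size), lr = lr,
                 optimizer = optimizer, weight_decay = weight_decay,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 num_classes = num_classes,
                 window_strategy = window_strategy,
                 cross_scale = isTRUE(cross_scale),
                 dsw_depth = as.integer(dsw_depth),
                 num_heads = as.integer(num_heads),
                 select_by = match.arg(select_by),
                 checkpoint = checkpoint),
            class = "train_config")
}

new_adamw <- function(params, lr, weight_decay, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$wd <- weight_decay
  st$b1 <- betas[1]; st$b2 <- betas[2]; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) 0 * p$value)
  st$v <- st$m
  st
}

adamw_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (nm in names(opt$params)) {
    p <- opt$params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[nm]] <- opt$b1 * opt$m[[nm]] + (1 - opt$b1) * g
    opt$v[[nm]] <- opt$b2 * opt$v[[nm]] + (1 - opt$b2) * g * g
    upd <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
    # decay weight matrices/tensors only, not biases or norm parameters
    wd <- if (is.null(dim(p$value))) 0 else opt$wd
    p$value <- p$value - opt$lr * (upd + wd * p$value)
  }
  invisible(opt)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

batch_logits <- function(model, x, batch_size = 32L) {
  B <- dim(x)[1]
  out <- NULL
  ag_set_training(FALSE)
  for (start in seq(1, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, B)
    lg <- ag_awpf_forward(ag_constant(x[idx, , , , drop = FALSE]), model)$logits$value
    out <- rbind(out, lg)
  }
  out
}

#' Fit an AWPF model on materialized image sets
#'
#' Runs minibatch AdamW on the cross-entropy loss, recording per-epoch
#' training loss and (when a validation set is given) validation macro
#' metrics; keeps a snapshot of the best weights under the selection
#' criterion.
#'
#' @param model An `awpf_model`.
#' @param train_set,val_set Materialized [load_image_folder()] sets (or any
#'   list with `x` `(B, 3, H, W)` and 1-based `y` as from
#'   [images_to_batch()]).
#' @param epochs,batch_size,lr,weight_decay,seed Optimisation settings.
#' @param select_by Validation metric used to pick the best epoch.
#' @return An `awpf_fit`: the model (best weights restored), a `history`
#'   tibble, and the final validation `metrics_report` (NULL without a
#'   validation set).
#' @export
fit_model <- function(model, train_set, val_set = NULL, epochs = 5L,
                      batch_size = 32L, lr = 0.001, weight_decay = 0.01,
                      seed = 0L, select_by = "mr") {
  tr <- if (is.data.frame(train_set)) images_to_batch(train_set) else train_set
  va <- if (is.data.frame(val_set)) images_to_batch(val_set) else val_set
  k <- model$cfg$num_classes
  if (max(tr$y) > k)
    stop("dataset has ", max(tr$y), " classes but the model head has ", k)
  params <- flatten_params(model)
  opt <- new_adamw(params, lr, weight_decay)
  n <- dim(tr$x)[1]
  hist <- list()
  best <- -Inf; best_values <- NULL; best_report <- NULL
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed * 10007L + ep, sample.int(n))
    losses <- c()
    ag_set_training(TRUE)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- tr$x[idx, , , , drop = FALSE]
      yb <- tr$y[idx]
      zero_grads(params)
      loss <- with_tape({
        out <- ag_awpf_forward(ag_constant(xb), model)
        ag_cross_entropy(out$logits, yb)
      })
      ag_backward(loss)
      adamw_step(opt)
      losses <- c(losses, loss$value)
    }
    ag_set_training(FALSE)
    row <- tibble(epoch = ep, train_loss = mean(losses),
                  val_acc = NA_real_, val_mp = NA_real_, val_mr = NA_real_,
                  val_mf = NA_real_)
    if (!is.null(va)) {
      lg <- batch_logits(model, va$x, batch_size)
      rep <- metrics_report(va$y - 1L, max.col(lg, ties.method = "first") - 1L,
                            k = k)
      row$val_acc <- rep$acc; row$val_mp <- rep$mp
      row$val_mr <- rep$mr; row$val_mf <- rep$mf
      crit <- switch(select_by, mr = rep$mr, acc = rep$acc,
                     mp = rep$mp, mf = rep$mf)
      if (crit > best) {
        best <- crit
        best_values <- lapply(params, function(p) p$value)
        best_report <- rep
      }
    }
    hist[[ep]] <- row
  }
  if (!is.null(best_values))
    for (nm in names(params)) params[[nm]]$value <- best_values[[nm]]
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 report = best_report, seed = seed),
            class = "awpf_fit")
}

#' @export
print.awpf_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("<awpf_fit> ", nrow(x$history), " epochs, final train loss ",
      sprintf("%.4f", last$train_loss), "\n", sep = "")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Tidy per-epoch training history
#' @param x An `awpf_fit`.
#' @param ... Unused.
#' @return The history tibble (epoch, train loss, validation metrics).
#' @export
tidy.awpf_fit <- function(x, ...) x$history

#' One-row fit summary
#' @param x An `awpf_fit`.
#' @param ... Unused.
#' @return Tibble with final loss and best validation metrics.
#' @export
glance.awpf_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(epochs = nrow(x$history), train_loss = last$train_loss,
         val_acc = if (is.null(x$report)) NA_real_ else x$report$acc,
         val_mr = if (is.null(x$report)) NA_real_ else x$report$mr)
}

#' Train an AWPF model from a dataset directory
#'
#' Loads `root/train` and `root/val` class-subdirectory trees, assembles the
#' model per the config's ablation flags, optimises with AdamW, and saves
#' the best-by-validation-macro-recall checkpoint when requested.
#'
#' @param cfg A [train_config()].
#' @param data_root Directory containing `train/` and `val/` image trees.
#' @return An `awpf_fit` (with `$checkpoint` path when one was written).
#' @export
train <- function(cfg, data_root) {
  stopifnot(inherits(cfg, "train_config"))
  size <- c(cfg$image_size, cfg$image_size)
  train_set <- load_image_folder(file.path(data_root, "train"), size)
  val_set <- load_image_folder(file.path(data_root, "val"), size)
  k <- cfg$num_classes %||% length(attr(train_set, "class_names"))
  if (k != length(attr(train_set, "class_names")))
    stop("config requests ", k, " classes but the dataset has ",
         length(attr(train_set, "class_names")))
  model <- awpf_resnet18(num_classes = k,
                         window_strategy = cfg$window_strategy,
                         cross_scale = cfg$cross_scale,
                         dsw_depth = cfg$dsw_depth,
                         num_heads = cfg$num_heads,
                         seed = cfg$seed)
  fit <- fit_model(model, train_set, val_set, epochs = cfg$epochs,
                   batch_size = cfg$batch_size, lr = cfg$lr,
                   weight_decay = cfg$weight_decay, seed = cfg$seed,
                   select_by = cfg$select_by)
  fit$config <- cfg
  if (!is.null(cfg$checkpoint)) {
    save_checkpoint(fit$model, cfg$checkpoint,
                    meta = list(seed = cfg$seed, epochs = cfg$epochs,
                                select_by = cfg$select_by))
    fit$checkpoint <- cfg$checkpoint
  }
  fit
}

#' Save model weights and metadata
#'
#' Serialises all parameter arrays (keyed by layer path), batch-norm running
#' statistics, the architecture config, and a metadata block including a
#' config hash.
#'
#' @param model An `awpf_model` or `resnet18`.
#' @param path Output file path.
#' @param meta Optional named list merged into the metadata block.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  params <- flatten_params(model)
  states <- flatten_states(model)
  obj <- list(type = class(model)[1],
              cfg = model$cfg,
              num_classes = model$num_classes,
              values = lapply(params, function(p) p$value),
              states = lapply(states, function(s)
                list(running_mean = s$running_mean,
                     running_var = s$running_var)),
              meta = c(meta, list(config_hash = rlang::hash(model$cfg))))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path Checkpoint file.
#' @return The reconstructed model with restored weights and running stats.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- if (identical(obj$type, "awpf_model")) {
    cfg <- obj$cfg
    awpf_resnet18(num_classes = cfg$num_classes,
                  window_strategy = cfg$window_strategy,
                  cross_scale = cfg$cross_scale,
                  dsw_depth = cfg$dsw_depth,
                  num_heads = cfg$num_heads,
                  mlp_ratio = cfg$mlp_ratio,
                  use_mlp = cfg$use_mlp,
                  shift_cap = cfg$shift_cap,
                  fuse_before_dsw = cfg$fuse_before_dsw,
                  adapter_channels = cfg$adapter_channels,
                  seed = cfg$seed)
  } else if (identical(obj$type, "resnet18")) {
    baseline_resnet18(obj$num_classes)
  } else stop("unknown checkpoint type: ", obj$type)
  params <- flatten_params(model)
  if (!setequal(names(params), names(obj$values)))
    stop("checkpoint parameters do not match the reconstructed architecture")
  for (nm in names(params)) params[[nm]]$value <- obj$values[[nm]]
  states <- flatten_states(model)
  for (nm in names(states)) {
    states[[nm]]$running_mean <- obj$states[[nm]]$running_mean
    states[[nm]]$running_var <- obj$states[[nm]]$running_var
  }
  model
}

#' Evaluate a model with replicate seeds and aggregate
#'
#' Runs inference on the validation tree once per seed replicate, computes
#' accuracy and macro precision/recall/F1, and aggregates them as mean and
#' sample standard deviation (n - 1; identical replicates give SD 0 —
#' inference itself is deterministic, so replicates differ only if the
#' caller varies the model between seeds).
#'
#' @param model An `awpf_model`, or a checkpoint path.
#' @param data_root Dataset root containing `val/` (or a class tree itself).
#' @param seeds Integer vector of replicate seeds.
#' @param image_size Input side length.
#' @param out Optional directory for JSON/CSV/PNG artifacts
#'   (see [write_metrics()]).
#' @return An `awpf_eval`: `summary` tibble (mean +/- SD per metric),
#'   per-replicate `reports`, and the score matrix of the last replicate.
#' @export
evaluate <- function(model, data_root, seeds = 0L, image_size = 224L,
                     out = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  vdir <- if (dir.exists(file.path(data_root, "val")))
    file.path(data_root, "val") else data_root
  set <- load_image_folder(vdir, c(image_size, image_size))
  k <- length(attr(set, "class_names"))
  if (k != model$cfg$num_classes)
    stop("dataset has ", k, " classes but the model head has ",
         model$cfg$num_classes)
  ba <- images_to_batch(set)
  reports <- list()
  scores <- NULL
  for (s in seeds) {
    lg <- with_seed(s, batch_logits(model, ba$x))
    scores <- softmax_rows(lg)
    reports[[length(reports) + 1L]] <-
      metrics_report(ba$y - 1L, max.col(lg, ties.method = "first") - 1L,
                     k = k, class_names = attr(set, "class_names"))
  }
  summary <- aggregate_reports(reports)
  if (!is.null(out))
    write_metrics(reports[[length(reports)]], out, scores, ba$y - 1L)
  structure(list(summary = summary, reports = reports, scores = scores,
                 y_true = ba$y - 1L, seeds = seeds),
            class = "awpf_eval")
}

#' @export
print.awpf_eval <- function(x, ...) {
  cat("<awpf_eval> ", length(x$reports), " replicate(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Grad-CAM localisation heatmap
#'
#' Weights the channels of a target feature map by the spatial mean of the
#' class-logit gradient, sums, rectifies, bilinearly upsamples to the input
#' size, and min-max normalises to `[0, 1]`. With the global-average-pool +
#' linear head, the channel weight for the fused map equals the head weight
#' row of the target class (divided by the pooled area).
#'
#' @param model An `awpf_model`.
#' @param image A single image: `(H, W, 3)`, `(3, H, W)`, or `(1, 3, H, W)`
#'   array in `[0, 1]`.
#' @param class_index 0-based target class.
#' @param target `"fused"` (the AWPF output, default) or `"backbone"` (F0).
#' @return `(H, W)` matrix in `[0, 1]`.
#' @export
grad_cam <- function(model, image, class_index,
                     target = c("fused", "backbone")) {
  target <- match.arg(target)
  d <- dim(image)
  x <- if (length(d) == 3 && d[3] == 3) {
    aperm(array(image, c(d, 1)), c(4, 3, 1, 2))
  } else if (length(d) == 3 && d[1] == 3) {
    array(image, c(1, d))
  } else if (length(d) == 4) image
  else stop("image must be (H, W, 3), (3, H, W) or (1, 3, H, W)")
  if (class_index < 0 || class_index >= model$cfg$num_classes)
    stop("class_index must lie in [0, ", model$cfg$num_classes, ")")
  ag_set_training(FALSE)
  nodes <- with_tape({
    r <- ag_awpf_forward(ag_constant(x), model)
    r$objective <- ag_col_sum(r$logits, class_index + 1L)
    r
  })
  ag_backward(nodes$objective)
  tnode <- if (target == "fused") nodes$fused else nodes$f0
  act <- tnode$value
  grd <- tnode$grad
  if (is.null(grd)) grd <- 0 * act
  C <- dim(act)[2]
  w <- vapply(seq_len(C), function(k) mean(grd[1, k, , ]), numeric(1))
  cam <- matrix(0, dim(act)[3], dim(act)[4])
  for (k in seq_len(C)) cam <- cam + w[k] * act[1, k, , ]
  cam <- pmax(cam, 0)
  Ah <- bilinear_matrix(nrow(cam), dim(x)[3])
  Aw <- bilinear_matrix(ncol(cam), dim(x)[4])
  cam <- Ah %*% cam %*% t(Aw)
  rng <- range(cam)
  if (rng[2] > rng[1]) (cam - rng[1]) / (rng[2] - rng[1]) else cam * 0
}
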