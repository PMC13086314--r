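# Independent oracles and shared fixtures for the test suite.

# Straight-line dense attention oracle: for every original position of a
# single-image feature map, gathers the positions it may attend to (same
# window after the cyclic shift, no wrap-around seam between them), computes
# softmax(QK'/sqrt(dk) + bias) V densely, and projects. Independent of the
# package's partition/mask machinery.
oracle_window_attention <- function(xmap, M, shift, w_qkv, b_qkv, w_out,
                                    b_out, bias_table, heads) {
  C <- dim(xmap)[1]; H <- dim(xmap)[2]; W <- dim(xmap)[3]
  dk <- C / heads
  N <- H * W
  X <- matrix(0, N, C)
  hh <- integer(N); ww <- integer(N)
  p <- 1L
  for (w in seq_len(W)) for (h in seq_len(H)) {
    X[p, ] <- xmap[, h, w]; hh[p] <- h; ww[p] <- w; p <- p + 1L
  }
  qkv <- sweep(X %*% w_qkv, 2, b_qkv, "+")
  # rolled coordinates and window/local indices
  hr <- ((hh - 1 - shift) %% H) + 1
  wr <- ((ww - 1 - shift) %% W) + 1
  win <- cbind((hr - 1) %/% M, (wr - 1) %/% M)
  li <- ((hr - 1) %% M) + 1
  lj <- ((wr - 1) %% M) + 1
  # no-seam condition: original displacement equals rolled displacement
  ridh <- hh - hr
  ridw <- ww - wr
  out <- matrix(0, N, C)
  for (pq in seq_len(N)) {
    allowed <- which(win[, 1] == win[pq, 1] & win[, 2] == win[pq, 2] &
                     ridh == ridh[pq] & ridw == ridw[pq])
    for (hd in seq_len(heads)) {
      cols <- ((hd - 1) * dk + 1):(hd * dk)
      q <- qkv[pq, cols]
      scores <- vapply(allowed, function(kq) {
        di <- li[pq] - li[kq]
        dj <- lj[pq] - lj[kq]
        bias_table[(di + M) + (2 * M - 1) * (dj + M - 1), hd] +
          sum(q * qkv[kq, C + cols]) / sqrt(dk)
      }, numeric(1))
      a <- exp(scores - max(scores))
      a <- a / sum(a)
      out[pq, cols] <- colSums(a * qkv[allowed, 2 * C + cols, drop = FALSE])
    }
  }
  Y <- sweep(out %*% w_out, 2, b_out, "+")
  res <- array(0, dim(xmap))
  for (p in seq_len(N)) res[, hh[p], ww[p]] <- Y[p, ]
  res
}

# Parameter count of the canonical 18-layer residual classifier, by direct
# enumeration of its layers (conv = cin*cout*k^2, batch-norm = 2c affine).
oracle_resnet18_params <- function(num_classes) {
  conv <- function(cin, cout, k) cin * cout * k^2
  bn <- function(c) 2 * c
  block <- function(cin, cout, downsample) {
    n <- conv(cin, cout, 3) + bn(cout) + conv(cout, cout, 3) + bn(cout)
    if (downsample) n <- n + conv(cin, cout, 1) + bn(cout)
    n
  }
  stage <- function(cin, cout, strided) {
    block(cin, cout, downsample = strided || cin != cout) +
      block(cout, cout, FALSE)
  }
  conv(3, 64, 7) + bn(64) +
    stage(64, 64, FALSE) + stage(64, 128, TRUE) +
    stage(128, 256, TRUE) + stage(256, 512, TRUE) +
    512 * num_classes + num_classes
}

# Identity-projection attention parameters: Q = K = V = x, output projection
# identity, zero bias table.
identity_attention_params <- function(C, M, heads = 1L) {
  p <- make_attention_params(C, M, heads)
  p$w_qkv$value <- cbind(diag(C), diag(C), diag(C))
  p$b_qkv$value <- rep(0, 3 * C)
  p$w_out$value <- diag(C)
  p$b_out$value <- rep(0, C)
  p$bias_table$value <- matrix(0, (2 * M - 1)^2, heads)
  p
}

# The default synthetic dataset (full per-class counts, 224 x 224), rendered
# once per test session and shared across files.
.fixture_env <- new.env(parent = emptyenv())

default_dataset_dir <- function() {
  if (is.null(.fixture_env$default_dir)) {
    dir <- file.path(tempdir(), "awpfnet-default-dataset")
    if (!dir.exists(file.path(dir, "train")))
      generate_synthetic_dataset(default_mushroom_spec(seed = 0L), dir)
    .fixture_env$default_dir <- dir
  }
  .fixture_env$default_dir
}

# A small reusable model for tests that only need a working forward pass.
tiny_model <- function(num_classes = 3L, seed = 7L) {
  if (is.null(.fixture_env$tiny) ||
      .fixture_env$tiny$cfg$num_classes != num_classes) {
    .fixture_env$tiny <- awpf_resnet18(num_classes = num_classes,
                                       adapter_channels = 32L,
                                       num_heads = 4L, seed = seed)
  }
  .fixture_env$tiny
}

rand_images <- function(n, side, seed = 1L) {
  set.seed(seed)
  array(runif(n * 3 * side * side), c(n, 3, side, side))
}
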