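# Dynamic Swin Window (DSW) blocks: resolution-adaptive window sizes,
# alternating shifted window partition, relative-position-biased attention
# inside each window, and bilinear upsampling to a fusion target size.

#' Feature map container
#'
#' A 4-axis array `(batch, channel, height, width)` tagged with its pyramid
#' level (0 = backbone output, 1 and 2 = downsampled levels).
#'
#' @param data Numeric 4-axis array `(B, C, H, W)`.
#' @param level Integer pyramid level in `0:2`.
#' @return A `feature_map` object.
#' @export
feature_map <- function(data, level = 0L) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  structure(data, level = as.integer(level), class = c("feature_map", "array"))
}

fm_level <- function(x) attr(x, "level") %||% 0L

fm_data <- function(x) {
  a <- unclass(x)
  attr(a, "level") <- NULL
  a
}

#' Resolution-adaptive window size
#'
#' The window strategy assigns a 7x7 window to the shallow pyramid level 1
#' and a 5x5 window to the deeper level 2 (`"mix"`), or a fixed size
#' everywhere (`"fixed5"`, `"fixed7"`), matching the ablation axes.
#'
#' @param level Pyramid level, 1 or 2.
#' @param strategy One of `"mix"`, `"fixed5"`, `"fixed7"`.
#' @return Integer window side M.
#' @export
#' @examples
#' select_window_size(1, "mix")  # 7
#' select_window_size(2, "mix")  # 5
select_window_size <- function(level, strategy = c("mix", "fixed5", "fixed7")) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed5") return(5L)
  if (strategy == "fixed7") return(7L)
  if (!level %in% c(1L, 2L))
    stop("window strategy 'mix' is defined for pyramid levels 1 and 2, got ", level)
  if (level == 1L) 7L else 5L
}

#' Alternating shift offset for a DSW block
#'
#' Even block indices use standard (non-shifted) windows; odd indices shift
#' by `min(cap, floor(H/2), floor(W/2))` so the shift never exceeds half the
#' feature map.
#'
#' @param block_index 0-based index of the block within a DSW stack.
#' @param Hi,Wi Feature-map height and width.
#' @param cap Maximum shift (default 3).
#' @return Integer shift offset.
#' @export
select_shift <- function(block_index, Hi, Wi, cap = 3L) {
  stopifnot(block_index >= 0, Hi >= 1, Wi >= 1)
  if (block_index %% 2 == 0) return(0L)
  as.integer(min(cap, Hi %/% 2, Wi %/% 2))
}

# Geometry of a rolled + padded window partition. For each padded-canvas
# coordinate we record the pre-roll coordinate (NA on padding) and a per-axis
# region id `orig - canvas`; two positions may attend to each other exactly
# when both are valid and their region ids agree on both axes (i.e. their
# displacement on the original map equals their in-window displacement, so
# no wrap-around lies between them).
window_geometry <- function(H, W, M, shift) {
  stopifnot(M >= 1)
  if (shift < 0 || shift >= M) stop("shift must satisfy 0 <= shift < M")
  M <- as.integer(M)
  H <- as.integer(H); W <- as.integer(W)
  pad_h <- (M - H %% M) %% M
  pad_w <- (M - W %% M) %% M
  Hp <- H + pad_h; Wp <- W + pad_w
  orig_h <- c(((seq_len(H) - 1 + shift) %% H) + 1, rep(NA_integer_, pad_h))
  orig_w <- c(((seq_len(W) - 1 + shift) %% W) + 1, rep(NA_integer_, pad_w))
  list(H = H, W = W, M = as.integer(M), shift = as.integer(shift),
       pad = c(pad_h, pad_w), rows = Hp %/% M, cols = Wp %/% M,
       orig_h = orig_h, orig_w = orig_w,
       rid_h = orig_h - seq_len(Hp), rid_w = orig_w - seq_len(Wp))
}

# Additive attention mask (M^2, M^2, n_windows): 0 where a query/key pair is
# allowed, -1e9 where the key is padding or lies across a wrap-around seam
# introduced by the cyclic shift. NULL when no masking is needed.
window_attention_mask <- function(geom) {
  M <- geom$M
  if (all(geom$pad == 0) && geom$shift == 0) return(NULL)
  M2 <- M * M
  nw <- geom$rows * geom$cols
  mask <- array(0, c(M2, M2, nw))
  for (ci in seq_len(geom$cols)) {
    for (ri in seq_len(geom$rows)) {
      hs <- (ri - 1) * M + seq_len(M)
      ws <- (ci - 1) * M + seq_len(M)
      rh <- geom$rid_h[hs]; rw <- geom$rid_w[ws]
      # token t = i + (j-1) M: row-in-window index varies fastest
      tok_rh <- rep(rh, times = M)
      tok_rw <- rep(rw, each = M)
      ok <- outer(tok_rh, tok_rh, "==") & outer(tok_rw, tok_rw, "==")
      ok[is.na(ok)] <- FALSE
      w <- ri + (ci - 1) * geom$rows
      mask[, , w][!ok] <- -1e9
    }
  }
  mask
}

# Token validity (non-padding) per window: logical (n_windows, M^2).
window_valid_mask <- function(geom) {
  M <- geom$M
  valid_h <- !is.na(geom$orig_h)
  valid_w <- !is.na(geom$orig_w)
  out <- matrix(FALSE, geom$rows * geom$cols, M * M)
  for (ci in seq_len(geom$cols)) {
    for (ri in seq_len(geom$rows)) {
      vh <- valid_h[(ri - 1) * M + seq_len(M)]
      vw <- valid_w[(ci - 1) * M + seq_len(M)]
      out[ri + (ci - 1) * geom$rows, ] <- rep(vh, times = M) & rep(vw, each = M)
    }
  }
  out
}

# Internal tokenisation of a canvas node: (B, C, H, W) -> (M^2, nW * B, C)
# with token t = i + (j-1)M inside each window, window id w = r + (c-1) rows,
# and window-batch index k = w + nW (b-1).
ag_canvas_to_tokens <- function(x, M, rows, cols) {
  d <- dim(x$value)
  B <- d[1]; C <- d[2]
  xp <- ag_aperm(x, c(3, 4, 1, 2))                     # (Hp, Wp, B, C)
  xr <- ag_reshape(xp, c(M, rows, M, cols, B, C))
  xs <- ag_aperm(xr, c(1, 3, 2, 4, 5, 6))              # (i, j, r, c, b, C)
  ag_reshape(xs, c(M * M, rows * cols * B, C))
}

ag_tokens_to_canvas <- function(tok, M, rows, cols, B, C) {
  xr <- ag_reshape(tok, c(M, M, rows, cols, B, C))
  xs <- ag_aperm(xr, c(1, 3, 2, 4, 5, 6))              # (i, r, j, c, b, C)
  xp <- ag_reshape(xs, c(M * rows, M * cols, B, C))
  ag_aperm(xp, c(3, 4, 1, 2))
}

#' Partition a feature map into shifted attention windows
#'
#' Cyclically rolls the map by `(-shift, -shift)`, zero-pads the bottom/right
#' edge to a multiple of `M`, and tiles it into `M x M` token windows. The
#' returned metadata (grid, padding, shift, validity mask, geometry) is
#' sufficient to invert the partition exactly with [reverse_windows()].
#'
#' @param f A [feature_map()] or `(B, C, H, W)` array.
#' @param M Window side length.
#' @param shift Cyclic shift offset, `0 <= shift < M`.
#' @return A `window_set`: list with `tokens` `(n_windows * B, M^2, C)`,
#'   `grid`, `pad`, `shift`, `valid_mask` `(n_windows, M^2, 1)` and geometry.
#' @export
partition_windows <- function(f, M, shift = 0L) {
  if (M <= 0) stop("window size M must be positive")
  x <- if (inherits(f, "feature_map")) fm_data(f) else f
  d <- dim(x)
  geom <- window_geometry(d[3], d[4], M, shift)
  node <- ag_constant(x)
  rolled <- ag_roll2d(node, geom$shift, geom$shift)
  padded <- ag_pad_br(rolled, geom$pad[1], geom$pad[2])
  tok <- ag_canvas_to_tokens(padded, geom$M, geom$rows, geom$cols)
  vm <- window_valid_mask(geom)
  structure(
    list(tokens = aperm(tok$value, c(2, 1, 3)),
         grid = c(geom$rows, geom$cols),
         pad = geom$pad,
         shift = geom$shift,
         valid_mask = array(vm, c(nrow(vm), ncol(vm), 1)),
         geom = geom,
         batch = d[1],
         level = if (inherits(f, "feature_map")) fm_level(f) else NULL),
    class = "window_set")
}

#' Invert a window partition
#'
#' Reassembles the original feature map from a `window_set`, discarding
#' padded positions and undoing the cyclic shift. `reverse_windows()` is the
#' exact inverse of [partition_windows()].
#'
#' @param ws A `window_set` from [partition_windows()].
#' @return A [feature_map()] with the original spatial size.
#' @export
reverse_windows <- function(ws) {
  g <- ws$geom
  tok <- ag_constant(aperm(ws$tokens, c(2, 1, 3)))
  C <- dim(ws$tokens)[3]
  canvas <- ag_tokens_to_canvas(tok, g$M, g$rows, g$cols, ws$batch, C)
  cropped <- ag_crop(canvas, g$H, g$W)
  out <- ag_roll2d(cropped, -g$shift, -g$shift)
  feature_map(out$value, ws$level %||% 0L)
}

# Relative-position index: (M^2, M^2) matrix of 1-based rows into a
# ((2M-1)^2, heads) bias table, from in-window coordinate offsets.
rel_position_index <- function(M) {
  i <- rep(seq_len(M), times = M)
  j <- rep(seq_len(M), each = M)
  di <- outer(i, i, "-")
  dj <- outer(j, j, "-")
  (di + M) + (2L * M - 1L) * (dj + M - 1L)
}

# Shared forward core of masked multi-head window attention.
# qkv: (M2 * NW, 3C) rows grouped by window-batch; table: ((2M-1)^2, heads).
window_mha_core <- function(qkv, table, rel_idx, mask, M2, NW, nW, heads,
                            store = FALSE) {
  C <- ncol(qkv) %/% 3L
  dk <- C %/% heads
  scale <- 1 / sqrt(dk)
  out <- matrix(0, nrow(qkv), C)
  Alist <- if (store) vector("list", NW * heads)
  bias <- lapply(seq_len(heads), function(h) matrix(table[rel_idx, h], M2, M2))
  for (k in seq_len(NW)) {
    rows <- ((k - 1L) * M2 + 1L):(k * M2)
    mk <- if (!is.null(mask)) mask[, , ((k - 1L) %% nW) + 1L] else NULL
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Q <- qkv[rows, cols, drop = FALSE]
      K <- qkv[rows, C + cols, drop = FALSE]
      V <- qkv[rows, 2L * C + cols, drop = FALSE]
      S <- tcrossprod(Q, K) * scale + bias[[h]]
      if (!is.null(mk)) S <- S + mk
      mx <- apply(S, 1, max)
      E <- exp(S - mx)
      A <- E / rowSums(E)
      dead <- mx < -1e8   # all keys masked: fall back to attending to self
      if (any(dead)) {
        A[dead, ] <- 0
        A[cbind(which(dead), which(dead))] <- 1
      }
      out[rows, cols] <- A %*% V
      if (store) Alist[[(k - 1L) * heads + h]] <- A
    }
  }
  list(out = out, A = Alist)
}

window_mha_backward <- function(g, qkv, rel_idx, Alist, M2, NW, nW, heads,
                                table_rows) {
  C <- ncol(qkv) %/% 3L
  dk <- C %/% heads
  scale <- 1 / sqrt(dk)
  dqkv <- matrix(0, nrow(qkv), 3L * C)
  dtab <- matrix(0, table_rows, heads)
  ui <- sort(unique(as.vector(rel_idx)))
  gidx <- as.vector(rel_idx)
  for (k in seq_len(NW)) {
    rows <- ((k - 1L) * M2 + 1L):(k * M2)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- Alist[[(k - 1L) * heads + h]]
      dO <- g[rows, cols, drop = FALSE]
      Q <- qkv[rows, cols, drop = FALSE]
      K <- qkv[rows, C + cols, drop = FALSE]
      V <- qkv[rows, 2L * C + cols, drop = FALSE]
      dV <- crossprod(A, dO)
      dA <- tcrossprod(dO, V)
      dS <- A * (dA - rowSums(dA * A))
      dqkv[rows, cols] <- dqkv[rows, cols] + dS %*% K * scale
      dqkv[rows, C + cols] <- dqkv[rows, C + cols] + crossprod(dS, Q) * scale
      dqkv[rows, 2L * C + cols] <- dqkv[rows, 2L * C + cols] + dV
      s <- rowsum(as.vector(dS), gidx)
      dtab[ui, h] <- dtab[ui, h] + as.vector(s)
    }
  }
  list(dqkv = dqkv, dtab = dtab)
}

ag_window_mha <- function(qkv, table, rel_idx, mask, M2, NW, nW, heads) {
  r <- window_mha_core(qkv$value, table$value, rel_idx, mask, M2, NW, nW,
                       heads, store = !is.null(.ag$tape))
  ag_node(r$out, list(qkv, table), function(g) {
    b <- window_mha_backward(g, qkv$value, rel_idx, r$A, M2, NW, nW, heads,
                             nrow(table$value))
    list(b$dqkv, b$dtab)
  })
}

#' Construct window-attention parameters
#'
#' Initialises the fused query/key/value projection, the output projection,
#' and the relative-position bias table for one attention sublayer.
#'
#' @param channels Token channel count C.
#' @param M Window side (bias table covers offsets in `[-(M-1), M-1]^2`).
#' @param num_heads Number of attention heads; must divide `channels`.
#' @param init_sd Standard deviation of the truncated-normal weight init.
#' @return A list of parameter nodes (`w_qkv`, `b_qkv`, `w_out`, `b_out`,
#'   `bias_table`) plus `num_heads` and `M`.
#' @export
make_attention_params <- function(channels, M, num_heads = 8L, init_sd = 0.02) {
  if (channels %% num_heads != 0)
    stop("channels (", channels, ") must be divisible by num_heads (", num_heads, ")")
  list(
    w_qkv = nn_parameter(trunc_normal(c(channels, 3L * channels), init_sd)),
    b_qkv = nn_parameter(rep(0, 3L * channels)),
    w_out = nn_parameter(trunc_normal(c(channels, channels), init_sd)),
    b_out = nn_parameter(rep(0, channels)),
    bias_table = nn_parameter(trunc_normal(c((2L * M - 1L)^2, num_heads), init_sd)),
    num_heads = as.integer(num_heads),
    M = as.integer(M))
}

#' Masked multi-head self-attention within windows
#'
#' Computes `Softmax(Q K' / sqrt(d_k) + B) V` independently per window and
#' head, where `B` is the learned relative-position bias. Keys that are
#' padding, or that lie across a cyclic-shift seam, are masked out of the
#' softmax; a query row whose keys are all masked attends to itself only.
#'
#' @param ws A `window_set` from [partition_windows()].
#' @param params Attention parameters from [make_attention_params()].
#' @return A `window_set` with transformed tokens and unchanged metadata.
#' @export
window_attention <- function(ws, params) {
  tok <- aperm(ws$tokens, c(2, 1, 3))        # (M2, NW, C)
  d <- dim(tok)
  M2 <- d[1]; NW <- d[2]; C <- d[3]
  if (C != nrow(params$w_qkv$value))
    stop("token channels (", C, ") do not match attention parameters")
  mask <- window_attention_mask(ws$geom)
  rel_idx <- rel_position_index(ws$geom$M)
  x2 <- matrix(tok, M2 * NW, C)
  qkv <- sweep(x2 %*% params$w_qkv$value, 2, params$b_qkv$value, "+")
  r <- window_mha_core(qkv, params$bias_table$value, rel_idx, mask,
                       M2, NW, prod(ws$grid), params$num_heads)
  out <- sweep(r$out %*% params$w_out$value, 2, params$b_out$value, "+")
  ws$tokens <- aperm(array(out, c(M2, NW, C)), c(2, 1, 3))
  ws
}

# ---- DSW transformer blocks -------------------------------------------------

#' Parameters for a stack of DSW blocks
#'
#' @param channels Token channel count.
#' @param M Window side used by every block in the stack.
#' @param depth Number of blocks (default 2: one regular, one shifted).
#' @param num_heads Attention heads per block.
#' @param mlp_ratio Hidden width of the feed-forward sublayer relative to
#'   `channels`.
#' @param use_mlp Include the feed-forward sublayer (default TRUE).
#' @return A `dsw_params` list of per-block parameter lists.
#' @export
make_dsw_params <- function(channels, M, depth = 2L, num_heads = 8L,
                            mlp_ratio = 4, use_mlp = TRUE) {
  hidden <- as.integer(round(channels * mlp_ratio))
  blocks <- lapply(seq_len(depth), function(b) {
    p <- list(
      ln1_g = nn_parameter(rep(1, channels)),
      ln1_b = nn_parameter(rep(0, channels)),
      attn = make_attention_params(channels, M, num_heads))
    if (use_mlp) {
      p$ln2_g <- nn_parameter(rep(1, channels))
      p$ln2_b <- nn_parameter(rep(0, channels))
      p$fc1_w <- nn_parameter(trunc_normal(c(channels, hidden), 0.02))
      p$fc1_b <- nn_parameter(rep(0, hidden))
      p$fc2_w <- nn_parameter(trunc_normal(c(hidden, channels), 0.02))
      p$fc2_b <- nn_parameter(rep(0, channels))
    }
    p
  })
  structure(list(blocks = blocks, M = as.integer(M), depth = as.integer(depth),
                 use_mlp = use_mlp),
            class = "dsw_params")
}

# One pre-norm transformer block on a map node: windowed attention with
# residual, then (optionally) an MLP with residual.
ag_dsw_block <- function(x, bp, M, shift) {
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  geom <- window_geometry(H, W, M, shift)
  mask <- window_attention_mask(geom)
  rel_idx <- rel_position_index(M)
  M2 <- M * M
  NW <- geom$rows * geom$cols * B

  t0 <- ag_reshape(ag_aperm(x, c(3, 4, 1, 2)), c(H * W * B, C))
  tn <- ag_layernorm(t0, bp$ln1_g, bp$ln1_b)
  xm <- ag_aperm(ag_reshape(tn, c(H, W, B, C)), c(3, 4, 1, 2))
  rolled <- ag_pad_br(ag_roll2d(xm, shift, shift), geom$pad[1], geom$pad[2])
  tok <- ag_canvas_to_tokens(rolled, M, geom$rows, geom$cols)
  tok2 <- ag_reshape(tok, c(M2 * NW, C))
  qkv <- ag_linear(tok2, bp$attn$w_qkv, bp$attn$b_qkv)
  att <- ag_window_mha(qkv, bp$attn$bias_table, rel_idx, mask, M2, NW,
                       geom$rows * geom$cols, bp$attn$num_heads)
  proj <- ag_linear(att, bp$attn$w_out, bp$attn$b_out)
  canvas <- ag_tokens_to_canvas(ag_reshape(proj, c(M2, NW, C)),
                                M, geom$rows, geom$cols, B, C)
  attn_map <- ag_roll2d(ag_crop(canvas, H, W), -shift, -shift)
  x1 <- ag_add(x, attn_map)

  if (is.null(bp$fc1_w)) return(x1)
  t1 <- ag_reshape(ag_aperm(x1, c(3, 4, 1, 2)), c(H * W * B, C))
  tm <- ag_layernorm(t1, bp$ln2_g, bp$ln2_b)
  h1 <- ag_gelu(ag_linear(tm, bp$fc1_w, bp$fc1_b))
  h2 <- ag_linear(h1, bp$fc2_w, bp$fc2_b)
  mlp_map <- ag_aperm(ag_reshape(h2, c(H, W, B, C)), c(3, 4, 1, 2))
  ag_add(x1, mlp_map)
}

ag_dsw_apply <- function(x, target_hw, params, shift_cap = 3L) {
  d <- dim(x$value)
  for (b in seq_along(params$blocks)) {
    shift <- select_shift(b - 1L, d[3], d[4], shift_cap)
    if (shift >= params$M) shift <- params$M - 1L
    x <- ag_dsw_block(x, params$blocks[[b]], params$M, shift)
  }
  ag_bilinear_resize(x, target_hw[1], target_hw[2])
}

#' Enhance a pyramid level with DSW blocks and upsample it
#'
#' Runs a stack of windowed-attention transformer blocks (alternating
#' regular and shifted partitions) over a feature map at its native
#' resolution, then bilinearly upsamples the enhanced map to `target_hw`
#' for fusion with the next-shallower level.
#'
#' @param f A [feature_map()] at pyramid level 1 or 2 (any level for fixed
#'   window strategies).
#' @param target_hw Integer `(H, W)` of the fusion target.
#' @param level Pyramid level used to select the window size.
#' @param cfg List with `window_strategy` (see [select_window_size()]) and
#'   optional `shift_cap`.
#' @param params A `dsw_params` stack from [make_dsw_params()]; its window
#'   size must match the strategy's choice for `level`.
#' @return A [feature_map()] of size `target_hw` at level `level`.
#' @export
dsw_apply <- function(f, target_hw, level, cfg = list(window_strategy = "mix"),
                      params) {
  if (any(target_hw < 1)) stop("target size must be at least 1 x 1")
  M <- select_window_size(level, cfg$window_strategy %||% "mix")
  if (M != params$M)
    stop("params were built for window size ", params$M, " but level ", level,
         " with strategy '", cfg$window_strategy %||% "mix", "' needs ", M)
  x <- ag_constant(if (inherits(f, "feature_map")) fm_data(f) else f)
  out <- ag_dsw_apply(x, target_hw, params, cfg$shift_cap %||% 3L)
  feature_map(out$value, level)
}
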