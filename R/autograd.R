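#' @useDynLib awpfnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Reverse-mode automatic differentiation over dense R arrays.
#
# A "node" is an environment holding $value (an array), $grad (accumulated
# cotangent, NULL until backward), and - when recorded on a tape - $parents
# and $backfn. Parameters are leaf nodes that persist across steps; the tape
# holds only the intermediate nodes of one forward pass, in creation order,
# so reverse iteration is a valid topological backward sweep.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$last_tape <- NULL
.ag$training <- FALSE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create a trainable parameter
#'
#' Wraps a numeric array in a leaf autodiff node whose gradient is
#' accumulated by [ag_backward()].
#'
#' @param value Numeric array or vector of initial weights.
#' @return A parameter node (environment with `$value` and `$grad`).
#' @keywords internal
nn_parameter <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$param <- TRUE
  n
}

ag_constant <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n
}

is_ag_node <- function(x) is.environment(x) && !is.null(x$value)

as_ag_node <- function(x) if (is_ag_node(x)) x else ag_constant(x)

ag_node <- function(value, parents = NULL, backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  tp <- .ag$tape
  if (!is.null(tp) && !is.null(backfn)) {
    n$parents <- parents
    n$backfn <- backfn
    if (tp$n >= length(tp$nodes))
      tp$nodes <- c(tp$nodes, vector("list", max(64L, length(tp$nodes))))
    tp$n <- tp$n + 1L
    tp$nodes[[tp$n]] <- n
  }
  n
}

#' Record a forward computation on a fresh tape
#'
#' Evaluates `expr` while recording every differentiable operation, so that
#' [ag_backward()] can run afterwards. Without `with_tape()` the same
#' operations execute in inference mode and store nothing.
#'
#' @param expr Expression building autodiff nodes.
#' @keywords internal
with_tape <- function(expr) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  old <- .ag$tape
  .ag$tape <- tp
  on.exit(.ag$tape <- old)
  res <- force(expr)
  .ag$last_tape <- tp
  res
}

#' Backpropagate from a node through the last recorded tape
#'
#' @param node Output node (typically a scalar loss).
#' @param grad Optional seed cotangent; defaults to 1 broadcast over the
#'   node's shape.
#' @keywords internal
ag_backward <- function(node, grad = NULL) {
  tp <- .ag$last_tape
  if (is.null(tp)) stop("no recorded tape: wrap the forward pass in with_tape()")
  if (is.null(grad)) {
    grad <- if (is.null(dim(node$value))) rep(1, length(node$value))
            else array(1, dim(node$value))
  }
  node$grad <- grad
  for (i in rev(seq_len(tp$n))) {
    n <- tp$nodes[[i]]
    if (is.null(n$grad) || is.null(n$backfn)) next
    gs <- n$backfn(n$grad)
    ps <- n$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(node)
}

ag_set_training <- function(on) {
  .ag$training <- isTRUE(on)
  invisible(on)
}

# ---- elementwise and shape operations ---------------------------------------

ag_add <- function(a, b) {
  a <- as_ag_node(a); b <- as_ag_node(b)
  ag_node(a$value + b$value, list(a, b),
          function(g) list(g, g))
}

ag_scale <- function(x, k) {
  ag_node(x$value * k, list(x), function(g) list(g * k))
}

ag_relu <- function(x) {
  keep <- x$value > 0
  ag_node(x$value * keep, list(x), function(g) list(g * keep))
}

ag_gelu <- function(x) {
  v <- x$value
  ph <- stats::pnorm(v)
  ag_node(v * ph, list(x),
          function(g) list(g * (ph + v * stats::dnorm(v))))
}

ag_reshape <- function(x, dims) {
  od <- dim(x$value)
  v <- x$value
  dim(v) <- dims
  ag_node(v, list(x), function(g) { dim(g) <- od; list(g) })
}

ag_aperm <- function(x, perm) {
  inv <- order(perm)
  ag_node(aperm(x$value, perm), list(x),
          function(g) list(aperm(g, inv)))
}

# Cyclic roll of the two spatial axes of a (B, C, H, W) array:
# y[..., h, w] = x[..., h + dh (mod H), w + dw (mod W)].
ag_roll2d <- function(x, dh, dw) {
  d <- dim(x$value)
  hi <- ((seq_len(d[3]) - 1 + dh) %% d[3]) + 1
  wi <- ((seq_len(d[4]) - 1 + dw) %% d[4]) + 1
  ag_node(x$value[, , hi, wi, drop = FALSE], list(x),
          function(g) {
            hb <- ((seq_len(d[3]) - 1 - dh) %% d[3]) + 1
            wb <- ((seq_len(d[4]) - 1 - dw) %% d[4]) + 1
            list(g[, , hb, wb, drop = FALSE])
          })
}

# Zero-pad the bottom/right spatial borders of a (B, C, H, W) array.
ag_pad_br <- function(x, ph, pw) {
  d <- dim(x$value)
  if (ph == 0 && pw == 0) return(x)
  out <- array(0, c(d[1], d[2], d[3] + ph, d[4] + pw))
  out[, , seq_len(d[3]), seq_len(d[4])] <- x$value
  ag_node(out, list(x),
          function(g) list(g[, , seq_len(d[3]), seq_len(d[4]), drop = FALSE]))
}

ag_crop <- function(x, H, W) {
  d <- dim(x$value)
  if (d[3] == H && d[4] == W) return(x)
  ag_node(x$value[, , seq_len(H), seq_len(W), drop = FALSE], list(x),
          function(g) {
            out <- array(0, d)
            out[, , seq_len(H), seq_len(W)] <- g
            list(out)
          })
}

# ---- dense linear algebra ---------------------------------------------------

ag_matmul <- function(a, b) {
  a <- as_ag_node(a); b <- as_ag_node(b)
  ag_node(a$value %*% b$value, list(a, b),
          function(g) list(g %*% t(b$value), crossprod(a$value, g)))
}

# y = x W + b for row-major samples: x (N, Cin), W (Cin, Cout), b (Cout).
ag_linear <- function(x, w, b = NULL) {
  y <- x$value %*% w$value
  if (!is.null(b)) y <- sweep(y, 2, b$value, "+")
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(y, parents, function(g) {
    out <- list(g %*% t(w$value), crossprod(x$value, g))
    if (!is.null(b)) out <- c(out, list(colSums(g)))
    out
  })
}

# Global average pooling (B, C, H, W) -> (B, C).
ag_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[3] * d[4]
  y <- matrix(rowSums(matrix(x$value, d[1] * d[2])), d[1], d[2]) / hw
  ag_node(y, list(x), function(g) {
    dx <- array(rep(as.vector(g), hw), d) / hw
    list(dx)
  })
}

# Mean of x over all elements (scalar output).
ag_mean_all <- function(x) {
  n <- length(x$value)
  d <- dim(x$value)
  ag_node(sum(x$value) / n, list(x),
          function(g) list(array(g / n, d %||% n)))
}

ag_col_sum <- function(x, j) {
  d <- dim(x$value)
  ag_node(sum(x$value[, j]), list(x), function(g) {
    dx <- array(0, d)
    dx[, j] <- g
    list(dx)
  })
}

# ---- convolution, pooling, resampling --------------------------------------

# 2-D convolution on (B, C, H, W); weights (Cout, Cin, KH, KW), matching the
# row layout .im2col_nchw() produces, so forward/backward are single GEMMs.
ag_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0) {
  xv <- x$value
  wd <- dim(w$value)
  d <- dim(xv)
  cout <- wd[1]; kh <- wd[3]; kw <- wd[4]
  oh <- (d[3] + 2 * pad - kh) %/% stride + 1
  ow <- (d[4] + 2 * pad - kw) %/% stride + 1
  cols <- .im2col_nchw(xv, dim(xv), kh, kw, stride, stride, pad, pad)
  wm <- matrix(w$value, cout)
  out <- wm %*% cols
  if (!is.null(b)) out <- out + b$value   # recycles down the Cout axis
  y <- aperm(array(out, c(cout, d[1], oh, ow)), c(2, 1, 3, 4))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(y, parents, function(g) {
    gm <- matrix(aperm(g, c(2, 1, 3, 4)), cout)
    dw <- gm %*% t(cols)
    dim(dw) <- wd
    dcols <- crossprod(wm, gm)
    dx <- .col2im_nchw(dcols, dim(xv), kh, kw, stride, stride, pad, pad)
    out <- list(dx, dw)
    if (!is.null(b)) out <- c(out, list(rowSums(gm)))
    out
  })
}

ag_maxpool <- function(x, k = 3, stride = 2, pad = 1) {
  r <- .maxpool_nchw(x$value, dim(x$value), k, k, stride, stride, pad, pad)
  d <- dim(x$value)
  ag_node(r$value, list(x),
          function(g) list(.maxpool_backward_nchw(g, r$argmax, d)))
}

# Interpolation matrix for 1-D bilinear resampling without corner alignment.
bilinear_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- floor(src)
  w1 <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  for (i in seq_len(n_out)) {
    A[i, i0[i] + 1] <- A[i, i0[i] + 1] + 1 - w1[i]
    A[i, i1[i] + 1] <- A[i, i1[i] + 1] + w1[i]
  }
  A
}

# Apply row/column mixing matrices over the spatial axes of (B, C, H, W):
# y[b,c,,] = Ah %*% x[b,c,,] %*% t(Aw). Separable, so both passes are GEMMs.
apply_hw_mats <- function(x, Ah, Aw) {
  d <- dim(x)
  H2 <- nrow(Ah); W2 <- nrow(Aw)
  xp <- aperm(x, c(3, 1, 2, 4))                   # (H, B, C, W)
  y1 <- Ah %*% matrix(xp, d[3])
  y1 <- array(y1, c(H2, d[1], d[2], d[4]))
  y1p <- aperm(y1, c(4, 2, 3, 1))                 # (W, B, C, H2)
  y2 <- Aw %*% matrix(y1p, d[4])
  y2 <- array(y2, c(W2, d[1], d[2], H2))
  aperm(y2, c(2, 3, 4, 1))
}

ag_bilinear_resize <- function(x, out_h, out_w) {
  d <- dim(x$value)
  if (d[3] == out_h && d[4] == out_w) return(x)
  Ah <- bilinear_matrix(d[3], out_h)
  Aw <- bilinear_matrix(d[4], out_w)
  ag_node(apply_hw_mats(x$value, Ah, Aw), list(x),
          function(g) list(apply_hw_mats(g, t(Ah), t(Aw))))
}

# ---- normalisation ----------------------------------------------------------

# Batch normalisation over (B, C, H, W) with per-channel affine parameters.
# `state` is an environment carrying running_mean / running_var, updated in
# training mode with momentum 0.1 (unbiased variance, as is conventional).
ag_batchnorm <- function(x, gamma, beta, state, eps = 1e-5, momentum = 0.1) {
  d <- dim(x$value)
  B <- d[1]; C <- d[2]; n <- B * d[3] * d[4]
  Mx <- matrix(x$value, B * C)
  if (.ag$training) {
    mu <- colSums(matrix(rowSums(Mx), B, C)) / n
    ex2 <- colSums(matrix(rowSums(Mx * Mx), B, C)) / n
    v <- pmax(ex2 - mu^2, 0)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * v * n / max(n - 1, 1)
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  invstd <- 1 / sqrt(v + eps)
  mu_r <- rep(mu, each = B); is_r <- rep(invstd, each = B)
  xhat <- (Mx - mu_r) * is_r
  y <- xhat * rep(gamma$value, each = B) + rep(beta$value, each = B)
  dim(y) <- d
  training <- .ag$training
  ag_node(y, list(x, gamma, beta), function(g) {
    Gm <- matrix(g, B * C)
    dgamma <- colSums(matrix(rowSums(Gm * xhat), B, C))
    dbeta <- colSums(matrix(rowSums(Gm), B, C))
    dxhat <- Gm * rep(gamma$value, each = B)
    if (training) {
      s1 <- rep(colSums(matrix(rowSums(dxhat), B, C)), each = B)
      s2 <- rep(colSums(matrix(rowSums(dxhat * xhat), B, C)), each = B)
      dx <- is_r / n * (n * dxhat - s1 - xhat * s2)
    } else {
      dx <- dxhat * is_r
    }
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# Layer normalisation over the channel axis of token matrices (N, C).
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$value
  N <- nrow(v); C <- ncol(v)
  mu <- rowMeans(v)
  var <- rowMeans(v * v) - mu^2
  invstd <- 1 / sqrt(pmax(var, 0) + eps)
  xhat <- (v - mu) * invstd
  gr <- rep(gamma$value, each = N)
  y <- xhat * gr + rep(beta$value, each = N)
  ag_node(y, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- g * gr
    dx <- invstd / C * (C * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
    list(dx, dgamma, dbeta)
  })
}

# ---- losses -----------------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy of logits (B, K) against 1-based integer labels.
ag_cross_entropy <- function(logits, labels) {
  p <- softmax_rows(logits$value)
  B <- nrow(p)
  picked <- p[cbind(seq_len(B), labels)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  ag_node(loss, list(logits), function(g) {
    dz <- p
    dz[cbind(seq_len(B), labels)] <- dz[cbind(seq_len(B), labels)] - 1
    list(g * dz / B)
  })
}
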