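# Window selection, shift rule, partition/reverse, and masked attention.

test_that("window size follows the resolution-adaptive strategy", {
  expect_identical(select_window_size(1, "mix"), 7L)
  expect_identical(select_window_size(2, "mix"), 5L)
  expect_identical(select_window_size(1, "fixed5"), 5L)
  expect_identical(select_window_size(2, "fixed5"), 5L)
  expect_identical(select_window_size(1, "fixed7"), 7L)
  expect_identical(select_window_size(2, "fixed7"), 7L)
  expect_error(select_window_size(3, "mix"), "levels 1 and 2")
  expect_error(select_window_size(0, "mix"), "levels 1 and 2")
})

test_that("shift alternates and is capped by half the map size", {
  expect_identical(select_shift(0, 14, 14, 3), 0L)
  expect_identical(select_shift(2, 14, 14, 3), 0L)
  expect_identical(select_shift(1, 14, 14, 3), 3L)
  expect_identical(select_shift(1, 4, 4, 3), 2L)
  expect_identical(select_shift(3, 5, 9, 3), 2L)
  expect_identical(select_shift(1, 1, 1, 3), 0L)
})

test_that("partition counts windows, pads, and masks padded positions", {
  f <- feature_map(array(rnorm(1 * 4 * 14 * 14), c(1, 4, 14, 14)), 1)
  ws <- partition_windows(f, 7, 0)
  expect_identical(dim(ws$tokens), c(4L, 49L, 4L))
  expect_identical(ws$pad, c(0L, 0L))
  expect_true(all(ws$valid_mask))

  f2 <- feature_map(array(rnorm(1 * 2 * 7 * 7), c(1, 2, 7, 7)), 2)
  ws2 <- partition_windows(f2, 5, 0)
  expect_identical(ws2$grid, c(2L, 2L))
  expect_identical(dim(ws2$tokens), c(4L, 25L, 2L))
  expect_identical(sum(!ws2$valid_mask), 51L)  # 100 padded cells - 49 real
  expect_error(partition_windows(f2, 0), "positive")
})

test_that("partition/reverse roundtrip is exact across sizes, windows, shifts", {
  for (side in c(5L, 8L, 11L, 16L)) {
    x <- array(as.numeric(seq_len(2 * 3 * side * side)), c(2, 3, side, side))
    f <- feature_map(x, 1)
    for (M in 1:8) {
      for (s in 0:(M - 1)) {
        if (s >= side) next
        ws <- partition_windows(f, M, s)
        back <- reverse_windows(ws)
        expect_identical(unclass(back)[seq_along(x)], as.numeric(x),
                         label = sprintf("side=%d M=%d s=%d", side, M, s))
      }
    }
  }
})

test_that("single-token and uniform attention reduce to closed forms", {
  # one token: softmax of a single logit is 1, output = value row
  C <- 4L
  p <- identity_attention_params(C, 1, heads = 1L)
  f <- feature_map(array(rnorm(C), c(1, C, 1, 1)), 1)
  ws <- window_attention(partition_windows(f, 1, 0), p)
  expect_equal(as.vector(ws$tokens), as.vector(unclass(f)), tolerance = 1e-12)

  # identical key rows: uniform softmax, every output = mean of values
  p2 <- identity_attention_params(2L, 2, heads = 1L)
  # make keys constant but values distinct: K columns of w_qkv map to zero
  p2$w_qkv$value[, 3:4] <- 0
  x <- array(rnorm(2 * 2 * 2 * 2), c(1, 2, 2, 2))
  ws2 <- window_attention(partition_windows(feature_map(x, 1), 2, 0), p2)
  vals <- matrix(aperm(ws2$tokens, c(2, 1, 3))[, 1, ], 4, 2)
  mean_v <- colMeans(matrix(aperm(partition_windows(feature_map(x, 1), 2, 0)$tokens,
                                  c(2, 1, 3))[, 1, ], 4, 2))
  for (r in 1:4) expect_equal(vals[r, ], mean_v, tolerance = 1e-12)
})

test_that("attention rows over unmasked keys are stochastic", {
  # recompute the attention matrix via the internal core and check row sums
  set.seed(3)
  M <- 5L; C <- 4L
  f <- feature_map(array(rnorm(1 * C * 7 * 7), c(1, C, 7, 7)), 2)
  ws <- partition_windows(f, M, 2)
  tok <- aperm(ws$tokens, c(2, 1, 3))
  p <- make_attention_params(C, M, 2L)
  qkv <- sweep(matrix(tok, 25 * 4, C) %*% p$w_qkv$value, 2, p$b_qkv$value, "+")
  mask <- awpfnet:::window_attention_mask(ws$geom)
  core <- awpfnet:::window_mha_core(qkv, p$bias_table$value,
                                    awpfnet:::rel_position_index(M), mask,
                                    25L, 4L, 4L, 2L, store = TRUE)
  for (A in core$A) expect_equal(rowSums(A), rep(1, 25), tolerance = 1e-6)
})

test_that("masked windowed attention matches the dense oracle", {
  # shifted and padded cases on small maps, vs. an independent dense oracle
  set.seed(11)
  C <- 4L
  cases <- expand.grid(H = c(3L, 5L, 7L, 8L), W = c(4L, 6L, 8L),
                       M = c(2L, 3L, 5L), heads = c(1L, 2L))
  for (r in seq_len(nrow(cases))) {
    H <- cases$H[r]; W <- cases$W[r]; M <- cases$M[r]; heads <- cases$heads[r]
    for (s in unique(c(0L, min(M - 1L, 2L)))) {
      p <- make_attention_params(C, M, heads)
      x <- array(rnorm(C * H * W), c(1, C, H, W))
      ws <- window_attention(partition_windows(feature_map(x, 1), M, s), p)
      got <- unclass(reverse_windows(ws))
      want <- oracle_window_attention(x[1, , , , drop = TRUE], M, s,
                                      p$w_qkv$value, p$b_qkv$value,
                                      p$w_out$value, p$b_out$value,
                                      p$bias_table$value, heads)
      expect_equal(got[1, , , ], want, tolerance = 1e-6,
                   label = sprintf("H=%d W=%d M=%d s=%d heads=%d", H, W, M, s, heads))
    }
  }
})

test_that("dsw_apply preserves channels and hits the target size", {
  set.seed(5)
  C <- 8L
  params5 <- make_dsw_params(C, 5L, depth = 2L, num_heads = 2L)
  f2 <- feature_map(array(rnorm(2 * C * 7 * 7), c(2, C, 7, 7)), 2)
  u1 <- dsw_apply(f2, c(14L, 14L), 2L, list(window_strategy = "mix"), params5)
  expect_identical(dim(u1), c(2L, C, 14L, 14L))
  expect_identical(attr(u1, "level"), 2L)

  params7 <- make_dsw_params(C, 7L, depth = 2L, num_heads = 2L)
  f1 <- feature_map(array(rnorm(1 * C * 14 * 14), c(1, C, 14, 14)), 1)
  u0 <- dsw_apply(f1, c(28L, 28L), 1L, list(window_strategy = "mix"), params7)
  expect_identical(dim(u0), c(1L, C, 28L, 28L))

  # target equal to input size: upsampling is the identity on the enhanced map
  same <- dsw_apply(f1, c(14L, 14L), 1L, list(window_strategy = "mix"), params7)
  blocks_only <- awpfnet:::ag_dsw_apply(awpfnet:::ag_constant(awpfnet:::fm_data(f1)),
                                        c(14L, 14L), params7, 3L)
  expect_equal(awpfnet:::fm_data(same), blocks_only$value, tolerance = 1e-12)

  expect_error(dsw_apply(f1, c(0L, 14L), 1L, list(window_strategy = "mix"),
                         params7), "at least 1")
  expect_error(dsw_apply(f1, c(14L, 14L), 1L, list(window_strategy = "fixed5"),
                         params7), "window size")
})

test_that("dsw_apply is batch-permutation equivariant", {
  set.seed(9)
  C <- 8L
  params <- make_dsw_params(C, 5L, depth = 2L, num_heads = 2L)
  x <- array(rnorm(3 * C * 7 * 7), c(3, C, 7, 7))
  out <- dsw_apply(feature_map(x, 2), c(9L, 9L), 2L,
                   list(window_strategy = "mix"), params)
  perm <- c(3L, 1L, 2L)
  out_p <- dsw_apply(feature_map(x[perm, , , , drop = FALSE], 2), c(9L, 9L),
                     2L, list(window_strategy = "mix"), params)
  expect_equal(awpfnet:::fm_data(out_p),
               awpfnet:::fm_data(out)[perm, , , , drop = FALSE],
               tolerance = 1e-10)
})
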