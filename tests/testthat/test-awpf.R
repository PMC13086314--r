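# Pyramid construction, bottom-up fusion, head, and end-to-end forward.

test_that("pyramid halves the spatial side with stride-2 conv arithmetic", {
  m <- tiny_model()
  side_out <- function(s) as.integer(floor((s + 2 - 3) / 2) + 1)
  for (side in c(28L, 8L, 7L)) {
    f0 <- feature_map(array(rnorm(1 * 32 * side * side), c(1, 32, side, side)), 0)
    p <- build_pyramid(f0, m)
    expect_identical(dim(p$f1)[3], side_out(side))
    expect_identical(dim(p$f2)[3], side_out(side_out(side)))
    expect_identical(attr(p$f1, "level"), 1L)
    expect_identical(attr(p$f2, "level"), 2L)
  }
  small <- feature_map(array(0, c(1, 32, 3, 3)), 0)
  expect_error(build_pyramid(small, m), "at least 4")
})

test_that("fusion with a stubbed zero DSW returns F0 unchanged", {
  m <- tiny_model()
  set.seed(2)
  f0 <- feature_map(array(rnorm(2 * 32 * 8 * 8), c(2, 32, 8, 8)), 0)
  p <- build_pyramid(f0, m)
  zero_dsw <- function(x, target_hw, level)
    awpfnet:::ag_constant(array(0, c(dim(x$value)[1:2], target_hw)))
  fused <- fuse(p, m, dsw_fn = zero_dsw)
  expect_equal(unclass(fused)[], unclass(p$f0)[], tolerance = 1e-12)
})

test_that("fusion is batch-permutation equivariant and shape-stable", {
  m <- tiny_model()
  set.seed(8)
  f0 <- feature_map(array(rnorm(3 * 32 * 8 * 8), c(3, 32, 8, 8)), 0)
  p <- build_pyramid(f0, m)
  fused <- fuse(p, m)
  expect_identical(dim(fused), dim(unclass(f0)))
  perm <- c(2L, 3L, 1L)
  pp <- build_pyramid(feature_map(awpfnet:::fm_data(f0)[perm, , , , drop = FALSE], 0), m)
  fused_p <- fuse(pp, m)
  expect_equal(awpfnet:::fm_data(fused_p),
               awpfnet:::fm_data(fused)[perm, , , , drop = FALSE],
               tolerance = 1e-8)
})

test_that("the head is global average pooling plus a linear map", {
  m <- tiny_model(num_classes = 3)
  K <- 3L; C <- 32L
  zero_map <- feature_map(array(0, c(2, C, 4, 4)), 0)
  lg <- classify(zero_map, m)
  expect_identical(dim(lg), c(2L, K))
  for (b in 1:2) expect_equal(lg[b, ], m$head$b$value, tolerance = 1e-12)

  v <- rnorm(C)
  const_map <- feature_map(aperm(array(v, c(C, 2, 4, 4)), c(2, 1, 3, 4)), 0)
  lg2 <- classify(const_map, m)
  want <- as.vector(v %*% m$head$w$value) + m$head$b$value
  expect_equal(lg2[1, ], want, tolerance = 1e-10)

  wrong <- feature_map(array(0, c(1, C + 1, 4, 4)), 0)
  expect_error(classify(wrong, m), "do not match head")
})

test_that("end-to-end forward obeys the shape contract and is deterministic", {
  m <- tiny_model(num_classes = 3)
  for (side in c(32L, 56L)) {
    lg <- predict(m, rand_images(2, side))
    expect_identical(dim(lg), c(2L, 3L))
  }
  x <- rand_images(2, 48, seed = 5)
  expect_equal(predict(m, x), predict(m, x), tolerance = 1e-6)
  pr <- predict(m, x, type = "prob")
  expect_equal(rowSums(pr), c(1, 1), tolerance = 1e-9)
  cl <- predict(m, x, type = "class")
  expect_true(all(cl %in% 1:3))
})

test_that("fixed-window ablation modes run the same path at one window size", {
  for (strat in c("fixed5", "fixed7")) {
    m <- awpf_resnet18(num_classes = 2, adapter_channels = 16L,
                       num_heads = 2L, window_strategy = strat, seed = 1)
    M <- if (strat == "fixed5") 5L else 7L
    expect_identical(m$dsw$level1$M, M)
    expect_identical(m$dsw$level2$M, M)
    lg <- predict(m, rand_images(1, 32))
    expect_identical(dim(lg), c(1L, 2L))
  }
  m_nc <- awpf_resnet18(num_classes = 2, adapter_channels = 16L,
                        num_heads = 2L, cross_scale = FALSE, seed = 1)
  expect_identical(dim(predict(m_nc, rand_images(1, 32))), c(1L, 2L))
})

test_that("every trainable parameter receives gradient on some batch", {
  # Input large enough that every pyramid level has multi-key attention
  # neighbourhoods: on degenerate 1x1/2x2 maps a shifted-window softmax can
  # reduce to a single key, making the bias-table gradient structurally zero.
  m <- awpf_resnet18(num_classes = 3, adapter_channels = 16L, num_heads = 2L,
                     seed = 2)
  params <- awpfnet:::flatten_params(m)
  got <- setNames(rep(FALSE, length(params)), names(params))
  for (trial in 1:2) {
    awpfnet:::zero_grads(params)
    awpfnet:::ag_set_training(TRUE)
    x <- rand_images(3, 112, seed = trial)
    y <- ((seq_len(3) + trial) %% 3) + 1L
    loss <- awpfnet:::with_tape(
      awpfnet:::ag_cross_entropy(awpfnet:::ag_awpf_forward(
        awpfnet:::ag_constant(x), m)$logits, y))
    awpfnet:::ag_backward(loss)
    for (nm in names(params)) {
      g <- params[[nm]]$grad
      if (!is.null(g) && any(g != 0)) got[nm] <- TRUE
    }
    if (all(got)) break
  }
  awpfnet:::ag_set_training(FALSE)
  expect_true(all(got), label = paste("dead:", paste(names(got)[!got], collapse = ", ")))
})

test_that("the default model stays under the 30M parameter budget", {
  m <- awpf_resnet18(num_classes = 7)
  expect_lt(count_parameters(m), 30e6)
  # the linear head alone: 256 * 7 weights + 7 biases
  expect_identical(count_parameters(list(m$head)), 1799)
})
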