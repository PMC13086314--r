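# Synthetic generator determinism and counts, splitting, folder loading.

test_that("tiny spec generation is deterministic and count-conserving", {
  spec <- dataset_spec(tibble::tibble(name = c("Boletus", "Tremella"),
                                      train_n = c(3L, 2L), val_n = c(1L, 1L)),
                       image_size = c(32L, 32L), seed = 0L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- generate_synthetic_dataset(spec, d1)
  s2 <- generate_synthetic_dataset(spec, d2)
  expect_identical(nrow(s1), 7L)
  expect_identical(table(s1$class, s1$split),
                   table(s2$class, s2$split))
  # byte-identical trees for identical (spec, seed)
  for (i in seq_len(nrow(s1))) {
    rel <- sub(d1, "", s1$path[i], fixed = TRUE)
    expect_identical(readBin(s1$path[i], "raw", 1e6),
                     readBin(file.path(d2, rel), "raw", 1e6),
                     label = rel)
  }
  # a different master seed changes pixel content
  spec2 <- spec; spec2$seed <- 1L
  d3 <- withr::local_tempdir()
  s3 <- generate_synthetic_dataset(spec2, d3)
  expect_false(identical(readBin(s1$path[1], "raw", 1e6),
                         readBin(s3$path[1], "raw", 1e6)))
  expect_true(file.exists(file.path(d1, "manifest.csv")))
  expect_error(generate_synthetic_dataset(
    dataset_spec(tibble::tibble(name = "Boletus", train_n = 0L, val_n = 0L)),
    withr::local_tempdir()), "zero images")
})

test_that("scaled default specs preserve the class imbalance structure", {
  spec <- default_mushroom_spec()
  expect_identical(nrow(spec$classes), 7L)
  expect_identical(sum(spec$classes$train_n), 1713L)
  expect_identical(sum(spec$classes$val_n), 722L)
  expect_identical(spec$classes$train_n[spec$classes$name == "Mix"], 14L)
  quarter <- default_mushroom_spec(scale = 0.25)
  expect_identical(quarter$classes$train_n[quarter$classes$name == "Lentinula_edodes"],
                   112L)
  expect_true(all(quarter$classes$val_n >= 1L))
})

test_that("stratified split rounds half up per class without leakage", {
  items <- tibble::tibble(
    path = sprintf("img%02d", 1:13),
    class = c(rep("a", 10), rep("b", 3)),
    class_index = c(rep(0L, 10), rep(1L, 3)))
  sp <- stratified_split(items, 0.7, seed = 1)
  expect_identical(sum(sp$train$class == "a"), 7L)
  expect_identical(sum(sp$val$class == "a"), 3L)
  expect_identical(sum(sp$train$class == "b"), 2L)
  # disjoint and exhaustive
  expect_identical(sort(c(sp$train$path, sp$val$path)), sort(items$path))
  expect_length(intersect(sp$train$path, sp$val$path), 0)

  one <- tibble::tibble(path = "x", class = "a", class_index = 0L)
  sp1 <- stratified_split(one, 0.7)
  expect_identical(nrow(sp1$train), 1L)
  expect_identical(nrow(sp1$val), 0L)
  expect_error(stratified_split(items, 1.2), "between 0 and 1")
  empty_cls <- structure(items, class_names = c("a", "b", "ghost"))
  expect_warning(stratified_split(empty_cls, 0.5), "ghost")
})

test_that("image folders load with stable ordering, resizing and scaling", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "zeta"))
  dir.create(file.path(root, "alpha"))
  png::writePNG(array(runif(10 * 10 * 3), c(10, 10, 3)),
                file.path(root, "zeta", "a.png"))
  png::writePNG(array(runif(30 * 20 * 3), c(30, 20, 3)),
                file.path(root, "alpha", "b.png"))
  set <- load_image_folder(root, c(24L, 24L))
  expect_identical(attr(set, "class_names"), c("alpha", "zeta"))
  expect_identical(set$class_index, c(0L, 1L))
  expect_identical(dim(set$image[[1]]), c(24L, 24L, 3L))
  expect_true(all(vapply(set$image, function(a) all(a >= 0 & a <= 1), logical(1))))

  # corrupted file among valid ones: count reduced by one, warning logged
  writeLines("not a png", file.path(root, "alpha", "broken.png"))
  expect_warning(set2 <- load_image_folder(root, c(24L, 24L)), "unreadable")
  expect_identical(nrow(set2), 2L)
  expect_error(load_image_folder(withr::local_tempdir()), "no class subdirectories")

  ba <- images_to_batch(set)
  expect_identical(dim(ba$x), c(2L, 3L, 24L, 24L))
  expect_identical(ba$y, c(1L, 2L))
})

test_that("the full default synthetic set matches the study composition", {
  dir <- default_dataset_dir()
  set <- load_image_folder(file.path(dir, "train"), materialize = FALSE)
  expect_identical(length(attr(set, "class_names")), 7L)
  expect_identical(nrow(set), 1713L)
  val <- load_image_folder(file.path(dir, "val"), materialize = FALSE)
  expect_identical(nrow(val), 722L)
  led <- list.files(file.path(dir, "train", "Lentinula_edodes"))
  expect_identical(length(led), 446L)
})

test_that("classes are separable by a linear probe on mean-colour features", {
  skip_if_not_installed("nnet")
  dir <- default_dataset_dir()
  mean_features <- function(split) {
    set <- load_image_folder(file.path(dir, split), materialize = FALSE)
    X <- t(vapply(set$path, function(p) {
      a <- png::readPNG(p)
      c(mean(a[, , 1]), mean(a[, , 2]), mean(a[, , 3]))
    }, numeric(3)))
    list(x = X, y = factor(set$class))
  }
  tr <- mean_features("train")
  va <- mean_features("val")
  fit <- nnet::multinom(y ~ ., data = data.frame(y = tr$y, tr$x),
                        maxit = 300, trace = FALSE)
  pred <- predict(fit, newdata = data.frame(va$x))
  expect_gte(mean(pred == va$y), 0.90)
})
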