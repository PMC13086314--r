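# Dataset handling: a deterministic procedural generator of class-separable
# synthetic mushroom images, stratified splitting, and an image-folder
# reader. The default generator spec reproduces the 7-class composition of
# the edible-mushroom study data (1,713 training / 722 validation images).

#' Dataset specification
#'
#' @param classes Data frame with columns `name`, `train_n`, `val_n`.
#' @param image_size Integer `(H, W)` of generated images.
#' @param seed Master seed; every image's content is a pure function of
#'   `(spec, seed)`.
#' @return A `dataset_spec`.
#' @export
dataset_spec <- function(classes, image_size = c(224L, 224L), seed = 0L) {
  classes <- as_tibble(classes)
  stopifnot(all(c("name", "train_n", "val_n") %in% names(classes)),
            all(classes$train_n >= 0), all(classes$val_n >= 0),
            !anyDuplicated(classes$name))
  structure(list(classes = classes,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Default 7-class edible-mushroom dataset specification
#'
#' Per-class train/validation counts of the study dataset (2,435 images in
#' total, split 7:3 per class), including the deliberately tiny "Mix" class
#' (14 train / 10 validation) that preserves the class imbalance driving the
#' macro-metric emphasis.
#'
#' @inheritParams dataset_spec
#' @param scale Multiply every per-class count by this factor (rounded,
#'   minimum 1 image per non-empty cell). `scale = 1` reproduces the full
#'   composition; fractional scales give a smaller dataset with the same
#'   relative class imbalance, used for desk-scale training runs.
#' @return A `dataset_spec`.
#' @export
default_mushroom_spec <- function(image_size = c(224L, 224L), seed = 0L,
                                  scale = 1) {
  train_n <- c(304L, 14L, 233L, 187L, 446L, 283L, 246L)
  val_n <- c(108L, 10L, 106L, 71L, 174L, 148L, 105L)
  if (scale != 1) {
    train_n <- pmax(1L, as.integer(round(train_n * scale)))
    val_n <- pmax(1L, as.integer(round(val_n * scale)))
  }
  dataset_spec(tibble(
    name = c("Hericium_erinaceus", "Mix", "Boletus", "Agaricus_bisporus",
             "Lentinula_edodes", "Pleurotus_eryngii", "Tremella"),
    train_n = train_n, val_n = val_n),
    image_size = image_size, seed = seed)
}

# Parametric rendering styles: cap/stipe geometry (fractions of the canvas),
# a class-specific palette, and a procedural texture. Palettes are chosen
# with distinct means so the classes are separable by a linear probe on
# mean-colour features.
mushroom_styles <- function() {
  list(
    Agaricus_bisporus = list(cap = c(0.93, 0.72, 0.72), stipe = c(0.95, 0.85, 0.84),
                             accent = c(0.78, 0.42, 0.44), cap_w = 0.58, cap_h = 0.40,
                             stipe_w = 0.16, stipe_h = 0.30, texture = "gills"),
    Boletus = list(cap = c(0.62, 0.22, 0.08), stipe = c(0.88, 0.78, 0.58),
                   accent = c(0.75, 0.42, 0.20), cap_w = 0.62, cap_h = 0.34,
                   stipe_w = 0.22, stipe_h = 0.34, texture = "spots"),
    Hericium_erinaceus = list(cap = c(0.98, 0.97, 0.94), stipe = c(0.95, 0.94, 0.90),
                              accent = c(0.90, 0.89, 0.84), cap_w = 0.64, cap_h = 0.60,
                              stipe_w = 0.10, stipe_h = 0.08, texture = "spines"),
    Lentinula_edodes = list(cap = c(0.26, 0.16, 0.08), stipe = c(0.70, 0.58, 0.40),
                            accent = c(0.80, 0.72, 0.55), cap_w = 0.64, cap_h = 0.38,
                            stipe_w = 0.11, stipe_h = 0.18, texture = "cracks"),
    Pleurotus_eryngii = list(cap = c(0.58, 0.45, 0.24), stipe = c(0.92, 0.90, 0.78),
                             accent = c(0.80, 0.74, 0.58), cap_w = 0.42, cap_h = 0.20,
                             stipe_w = 0.34, stipe_h = 0.54, texture = "plain"),
    Tremella = list(cap = c(0.95, 0.85, 0.25), stipe = c(0.92, 0.84, 0.35),
                    accent = c(0.80, 0.66, 0.12), cap_w = 0.68, cap_h = 0.52,
                    stipe_w = 0.12, stipe_h = 0.10, texture = "ridges"))
}

# Render one S x S RGB mushroom image under the current RNG state.
render_mushroom <- function(S, style) {
  sq <- (seq_len(S) - 0.5) / S
  u <- matrix(sq, S, S, byrow = TRUE)   # horizontal coordinate in [0,1]
  v <- matrix(sq, S, S)                 # vertical coordinate, top = 0

  img <- array(0, c(S, S, 3))
  bg <- c(0.26, 0.28, 0.20) * stats::runif(1, 0.8, 1.2)
  for (ch in 1:3) img[, , ch] <- bg[ch]
  for (b in 1:3) {   # background clutter blobs
    bx <- stats::runif(1); by <- stats::runif(1)
    sg <- stats::runif(1, 0.05, 0.15)
    w <- 0.4 * exp(-((u - bx)^2 + (v - by)^2) / (2 * sg^2))
    col <- stats::runif(3, 0.1, 0.5)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - w) + col[ch] * w
  }

  scale <- stats::runif(1, 0.85, 1.15)
  cx <- 0.5 + stats::runif(1, -0.08, 0.08)
  cy <- 0.40 + stats::runif(1, -0.06, 0.06)
  ax <- style$cap_w * scale / 2
  ay <- style$cap_h * scale / 2
  sw <- style$stipe_w * scale
  sh <- style$stipe_h * scale

  stipe <- abs(u - cx) <= sw / 2 & v >= cy & v <= cy + sh
  cap <- ((u - cx) / ax)^2 + ((v - cy) / ay)^2 <= 1
  cj <- stats::runif(3, -0.04, 0.04)    # per-image palette jitter
  for (ch in 1:3) {
    img[, , ch][stipe] <- style$stipe[ch] + cj[ch]
    img[, , ch][cap] <- style$cap[ch] + cj[ch]
  }

  tex <- switch(style$texture,
    spots = , cracks = {
      m <- matrix(FALSE, S, S)
      nspots <- 14L
      for (s in seq_len(nspots)) {
        px <- cx + ax * stats::runif(1, -0.8, 0.8)
        py <- cy + ay * stats::runif(1, -0.8, 0.8)
        r <- stats::runif(1, 0.012, 0.03)
        rx <- if (style$texture == "cracks") r * 2.5 else r
        m <- m | (((u - px) / rx)^2 + ((v - py) / r)^2 <= 1)
      }
      m & cap
    },
    gills = cap & v > cy & (sin(42 * pi * u) > 0.2),
    spines = cap & (matrix(stats::runif(S * S), S, S) > 0.65),
    ridges = cap & (sin(16 * pi * (v + 0.15 * sin(6 * pi * u))) > 0.25),
    plain = matrix(FALSE, S, S))
  for (ch in 1:3) img[, , ch][tex] <- style$accent[ch] + cj[ch]

  illum <- stats::runif(1, 0.88, 1.12)
  shade <- 1 - 0.15 * v
  for (ch in 1:3) img[, , ch] <- img[, , ch] * illum * shade
  img <- img + array(stats::rnorm(S * S * 3, 0, 0.02), c(S, S, 3))
  pmin(pmax(img, 0), 1)
}

image_seed <- function(master, class_idx, split, idx) {
  base <- (as.double(master) * 1000003 + class_idx * 131071 +
             (if (split == "train") 0 else 499979) + idx * 7919)
  as.integer(base %% 2147483629)
}

#' Generate a synthetic mushroom image dataset
#'
#' Writes a `root/<split>/<class>/<idx>.png` tree of procedurally rendered
#' mushroom images: per class a parametric silhouette (cap ellipse + stipe
#' rectangle) with a class-specific palette and texture (spots, gills,
#' spines, cracks or ridges), over cluttered backgrounds with seeded jitter
#' in pose, scale and illumination. The `Mix` class draws its renderer
#' uniformly from the other six classes. Identical `(spec, seed)` yields
#' byte-identical files.
#'
#' @param spec A [dataset_spec()]; defaults to [default_mushroom_spec()].
#' @param dir Output directory root.
#' @return A `labeled_image_set` tibble (`path`, `class`, `class_index`,
#'   `split`) with a `class_names` attribute; a `manifest.csv` is written
#'   beside the tree.
#' @export
generate_synthetic_dataset <- function(spec = default_mushroom_spec(), dir) {
  stopifnot(inherits(spec, "dataset_spec"))
  if (sum(spec$classes$train_n) + sum(spec$classes$val_n) == 0)
    stop("spec requests zero images")
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  S <- spec$image_size[1]
  if (spec$image_size[2] != S)
    stop("only square image sizes are supported by the renderer")
  styles <- mushroom_styles()
  base_names <- setdiff(spec$classes$name, "Mix")
  unknown <- setdiff(base_names, names(styles))
  if (length(unknown))
    stop("no rendering style for class(es): ", paste(unknown, collapse = ", "))
  class_names <- sort(spec$classes$name)
  rows <- list()
  for (ci in seq_len(nrow(spec$classes))) {
    cname <- spec$classes$name[ci]
    cidx <- match(cname, class_names) - 1L
    for (split in c("train", "val")) {
      n <- if (split == "train") spec$classes$train_n[ci] else spec$classes$val_n[ci]
      if (n == 0) next
      d <- file.path(dir, split, cname)
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_len(n)) {
        p <- file.path(d, sprintf("%04d.png", i))
        with_seed(image_seed(spec$seed, ci, split, i), {
          st <- if (cname == "Mix") {
            pick <- base_names[sample.int(length(base_names), 1)]
            styles[[pick]]
          } else styles[[cname]]
          png::writePNG(render_mushroom(S, st), p)
        })
        rows[[length(rows) + 1L]] <- tibble(path = p, class = cname,
                                            class_index = cidx, split = split)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  utils::write.csv(out[, c("path", "class", "split")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  structure(dplyr::arrange(out, .data$split, .data$class, .data$path),
            class_names = class_names,
            class = c("labeled_image_set", "tbl_df", "tbl", "data.frame"))
}

#' Stratified train/validation split
#'
#' Splits per class with round-half-up allocation to the training set
#' (`floor(n * fraction + 0.5)` items) after a seeded shuffle; the two parts
#' are disjoint and jointly exhaustive.
#'
#' @param items A `labeled_image_set` (or any data frame with a `class`
#'   column).
#' @param train_fraction Fraction assigned to training, in (0, 1);
#'   default 0.7 (the study's 7:3 protocol).
#' @param seed Shuffle seed.
#' @return List with elements `train` and `val`.
#' @export
stratified_split <- function(items, train_fraction = 0.7, seed = 0L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  nm <- attr(items, "class_names") %||% sort(unique(items$class))
  empty <- setdiff(nm, unique(items$class))
  if (length(empty))
    warning("class(es) with 0 items skipped: ", paste(empty, collapse = ", "))
  tr <- list(); va <- list()
  for (cn in nm) {
    sub <- items[items$class == cn, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0) next
    ntr <- floor(n * train_fraction + 0.5)
    ord <- with_seed(image_seed(seed, match(cn, nm), "train", 1L),
                     sample.int(n))
    tr[[cn]] <- sub[ord[seq_len(ntr)], , drop = FALSE]
    if (ntr < n) va[[cn]] <- sub[ord[(ntr + 1):n], , drop = FALSE]
  }
  keep <- function(x) structure(dplyr::bind_rows(x), class_names = nm,
                                class = class(items))
  list(train = keep(tr), val = keep(va))
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg", "tif", "tiff")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("EBImage is required to read ", ext, " files")
    aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
  } else stop("unsupported image format: ", ext)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  a
}

resize_image <- function(a, out_h, out_w) {
  d <- dim(a)
  if (d[1] == out_h && d[2] == out_w) return(a)
  Ah <- bilinear_matrix(d[1], out_h)
  Aw <- bilinear_matrix(d[2], out_w)
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Ah %*% a[, , ch] %*% t(Aw)
  out
}

#' Load a class-subdirectory image folder
#'
#' Reads `root/<class>/*.png|jpg` with alphabetical class ordering (stable
#' 0-based class indices), decodes to RGB, resizes to `image_size` by
#' bilinear interpolation, and scales intensities to `[0, 1]`. Unreadable
#' files are skipped with a warning.
#'
#' @param root Directory containing one subdirectory per class.
#' @param image_size Integer `(H, W)` target size (default 224 x 224).
#' @param materialize Attach decoded arrays as an `image` list-column
#'   (default TRUE); otherwise only paths are returned.
#' @return A `labeled_image_set` tibble.
#' @export
load_image_folder <- function(root, image_size = c(224L, 224L),
                              materialize = TRUE) {
  dirs <- sort(list.dirs(root, recursive = FALSE, full.names = TRUE))
  if (length(dirs) == 0) stop("no class subdirectories found under ", root)
  class_names <- basename(dirs)
  rows <- list()
  for (ci in seq_along(dirs)) {
    files <- sort(list.files(dirs[ci], pattern = "\\.(png|jpe?g|tiff?)$",
                             full.names = TRUE, ignore.case = TRUE))
    for (f in files) {
      img <- if (materialize) {
        tryCatch(resize_image(read_image_file(f), image_size[1], image_size[2]),
                 error = function(e) {
                   warning("skipping unreadable file ", f, ": ",
                           conditionMessage(e))
                   NULL
                 })
      } else NA
      if (materialize && is.null(img)) next
      rows[[length(rows) + 1L]] <- tibble(
        path = f, class = class_names[ci], class_index = ci - 1L,
        image = if (materialize) list(img) else list(NULL))
    }
  }
  if (length(rows) == 0) stop("no readable images found under ", root)
  out <- dplyr::bind_rows(rows)
  if (!materialize) out$image <- NULL
  structure(out, class_names = class_names,
            class = c("labeled_image_set", "tbl_df", "tbl", "data.frame"))
}

#' Stack a labeled image set into a model input batch
#'
#' @param set A materialized `labeled_image_set` (with `image` list-column).
#' @return List with `x` `(B, 3, H, W)` array and `y` 1-based integer labels.
#' @export
images_to_batch <- function(set) {
  stopifnot("image" %in% names(set))
  d <- dim(set$image[[1]])
  B <- nrow(set)
  x <- array(0, c(B, 3, d[1], d[2]))
  for (i in seq_len(B)) x[i, , , ] <- aperm(set$image[[i]], c(3, 1, 2))
  list(x = x, y = set$class_index + 1L)
}
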