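# Dataset indexing, preprocessing, augmentation and split/fold planning for
# class-per-folder image trees.

imageExtensions <- c("png", "jpg", "jpeg")

readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", path)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(img)[3] != 3L) stop("expected a 3-channel image: ", path)
  img * 255
}

#' Index a class-per-folder image dataset
#'
#' Enumerates every readable PNG/JPEG under one subdirectory per class.
#' Class order is lexicographic (C locale) over folder names and class ids
#' are dense in `[0, Y)`.  Unreadable images are collected in a skip report
#' rather than silently dropped; an empty class folder is an error.
#'
#' @param root Dataset root directory.
#' @return A [DatasetIndex-class].
#' @export
indexDataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  classDirs <- sort(list.dirs(root, recursive = FALSE), method = "radix")
  if (!length(classDirs)) stop("no class subdirectories under ", root)
  classNames <- basename(classDirs)
  paths <- character(0); ids <- integer(0); skipped <- character(0)
  for (k in seq_along(classDirs)) {
    pat <- paste0("\\.(", paste(imageExtensions, collapse = "|"), ")$")
    files <- sort(list.files(classDirs[k], full.names = TRUE, pattern = pat,
                             ignore.case = TRUE),
                  method = "radix")
    ok <- logical(length(files))
    for (i in seq_along(files)) {
      ok[i] <- !inherits(try(readImageFile(files[i]), silent = TRUE),
                         "try-error")
    }
    skipped <- c(skipped, files[!ok])
    files <- files[ok]
    if (!length(files))
      stop("class folder '", classNames[k], "' contains no readable images")
    paths <- c(paths, files)
    ids <- c(ids, rep.int(k - 1L, length(files)))
  }
  new("DatasetIndex",
      records = data.frame(path = paths, classId = ids,
                           stringsAsFactors = FALSE),
      classNames = classNames, skipped = skipped)
}

#' Load images from an index into a batch array
#'
#' @param index A [DatasetIndex-class].
#' @param ids Record indices (1-based); defaults to all.
#' @return List with `images` (`N x H x W x 3` array on the \[0, 255\] scale)
#'   and `labels` (0-based class ids).
#' @export
loadImages <- function(index, ids = seq_len(nrow(index@records))) {
  first <- readImageFile(index@records$path[ids[1]])
  out <- array(0, c(length(ids), dim(first)))
  out[1, , , ] <- first
  for (i in seq_along(ids)[-1]) {
    img <- readImageFile(index@records$path[ids[i]])
    if (!identical(dim(img), dim(first)))
      stop("images in a batch must share a common size")
    out[i, , , ] <- img
  }
  list(images = out, labels = index@records$classId[ids])
}

#' Stratified hold-out split
#'
#' Draws a per-class stratified train/test split: for each class,
#' `round(testFraction * n)` images go to the test set.
#'
#' @param index A [DatasetIndex-class].
#' @param testFraction Test fraction in (0, 1); default 0.3 (a 70:30 split).
#' @param seed Integer seed, recorded in the plan for exact replay.
#' @return A [SplitPlan-class].
#' @export
makeSplit <- function(index, testFraction = 0.3, seed = 1L) {
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be in (0, 1)")
  labels <- index@records$classId
  trainIds <- integer(0); testIds <- integer(0)
  withr::with_seed(seed, {
    for (k in sort(unique(labels))) {
      idx <- which(labels == k)
      if (length(idx) < 2L)
        stop("class ", index@classNames[k + 1L],
             " has fewer than 2 images; cannot split")
      idx <- sample(idx)
      nTest <- round(testFraction * length(idx))
      testIds <- c(testIds, idx[seq_len(nTest)])
      trainIds <- c(trainIds, idx[-seq_len(nTest)])
    }
  })
  new("SplitPlan", trainIds = sort(trainIds), testIds = sort(testIds),
      folds = list(), labels = as.integer(labels), seed = as.integer(seed))
}

#' Stratified k-fold plan over the training pool
#'
#' Partitions the training pool of an existing split into `k` stratified
#' folds; each fold trains on (k-1)/k and validates on 1/k of the pool, and
#' the test set is untouched and identical across folds.
#'
#' @param plan A [SplitPlan-class] from [makeSplit()].
#' @param k Number of folds (default 5).
#' @return The plan with its `folds` slot filled.
#' @export
makeFolds <- function(plan, k = 5L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  labels <- plan@labels[plan@trainIds]
  assignment <- integer(length(plan@trainIds))
  withr::with_seed(plan@seed + 1L, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      if (length(idx) < k)
        stop("class ", cls, " has fewer than k = ", k, " training images")
      assignment[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    list(train = plan@trainIds[assignment != f],
         val = plan@trainIds[assignment == f])
  })
  methods::initialize(plan, folds = folds)
}

#' Write / read a split plan as JSON
#'
#' The JSON records all index sets, labels and the seed, so an experiment is
#' exactly replayable.
#'
#' @param plan A [SplitPlan-class].
#' @param path JSON file path.
#' @return `readSplitPlan` returns the reconstructed [SplitPlan-class].
#' @export
writeSplitPlan <- function(plan, path) {
  jsonlite::write_json(
    list(trainIds = plan@trainIds, testIds = plan@testIds,
         folds = lapply(plan@folds, function(f)
           list(train = f$train, val = f$val)),
         labels = plan@labels, seed = plan@seed),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeSplitPlan
#' @export
readSplitPlan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- list()
  if (length(x$folds)) {
    folds <- if (is.data.frame(x$folds)) {
      lapply(seq_len(nrow(x$folds)), function(i)
        list(train = as.integer(x$folds$train[[i]]),
             val = as.integer(x$folds$val[[i]])))
    } else {
      lapply(x$folds, function(f) list(train = as.integer(f$train),
                                       val = as.integer(f$val)))
    }
  }
  new("SplitPlan", trainIds = as.integer(x$trainIds),
      testIds = as.integer(x$testIds), folds = folds,
      labels = as.integer(x$labels), seed = as.integer(x$seed))
}

## ---- preprocessing ----

# ImageNet channel means in BGR order (the caffe-style convention of the
# reference backbone implementations)
imagenetMeansBGR <- c(103.939, 116.779, 123.68)

#' Backbone preprocessing: RGB to BGR and zero-centering
#'
#' Reorders channels RGB -> BGR and subtracts the ImageNet channel means
#' (103.939, 116.779, 123.68 in BGR order), with no scaling — the convention
#' the reference backbone implementations were trained under.
#'
#' @param images `N x H x W x 3` batch or `H x W x 3` single image, RGB on
#'   the \[0, 255\] scale.
#' @param means Channel means in BGR order.
#' @return Array of the same shape, BGR, zero-centered.
#' @export
preprocessImages <- function(images, means = imagenetMeansBGR) {
  single <- length(dim(images)) == 3L
  if (single) images <- array(images, c(1L, dim(images)))
  if (dim(images)[4] != 3L) stop("expected 3-channel RGB input")
  out <- images[, , , c(3L, 2L, 1L), drop = FALSE]
  for (c in 1:3) out[, , , c] <- out[, , , c] - means[c]
  if (single) array(out, dim(out)[2:4]) else out
}

#' Invert backbone preprocessing
#'
#' @param images Preprocessed BGR array.
#' @inheritParams preprocessImages
#' @return RGB array on the \[0, 255\] scale.
#' @export
unpreprocessImages <- function(images, means = imagenetMeansBGR) {
  single <- length(dim(images)) == 3L
  if (single) images <- array(images, c(1L, dim(images)))
  for (c in 1:3) images[, , , c] <- images[, , , c] + means[c]
  out <- images[, , , c(3L, 2L, 1L), drop = FALSE]
  if (single) array(out, dim(out)[2:4]) else out
}

## ---- augmentation ----

#' Augmentation configuration
#'
#' Defaults follow the training recipe: random flip, rotation up to 20
#' degrees, scale up to 0.20, translation up to 0.20, followed by a random
#' crop to 224 pixels.  The wider +/-25 degree / +/-0.25 magnitudes and a
#' Gaussian blur instead of additive noise are available as alternates.
#'
#' @param rotationDeg Maximum absolute rotation in degrees.
#' @param scaleFrac Maximum absolute relative scale change.
#' @param translateFrac Maximum absolute translation as a fraction of size.
#' @param flip Random horizontal flip.
#' @param noiseSd Additive Gaussian pixel noise sd on the \[0, 255\] scale.
#' @param blurSigma Gaussian blur sigma in pixels (0 disables).
#' @param cropSize Final random-crop side in pixels.
#' @return A validated augmentation configuration list.
#' @export
augmentConfig <- function(rotationDeg = 20, scaleFrac = 0.20,
                          translateFrac = 0.20, flip = TRUE, noiseSd = 5,
                          blurSigma = 0, cropSize = 224L) {
  if (any(c(rotationDeg, scaleFrac, translateFrac, noiseSd, blurSigma) < 0))
    stop("augmentation magnitudes must be nonnegative")
  list(rotationDeg = rotationDeg, scaleFrac = scaleFrac,
       translateFrac = translateFrac, flip = isTRUE(flip), noiseSd = noiseSd,
       blurSigma = blurSigma, cropSize = as.integer(cropSize))
}

identityAugment <- function(cropSize) {
  augmentConfig(rotationDeg = 0, scaleFrac = 0, translateFrac = 0,
                flip = FALSE, noiseSd = 0, blurSigma = 0, cropSize = cropSize)
}

# Inverse-mapped affine sampling with bilinear interpolation and border
# replication: output pixel (r, c) samples the input at the location obtained
# by rotating by -theta and scaling by 1/s about the image center, then
# shifting by the translation.
affineSample <- function(img, theta, scale, tx, ty) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(rep(seq_len(H), W), H, W) - cy
  c <- matrix(rep(seq_len(W), each = H), H, W) - cx
  ct <- cos(-theta); st <- sin(-theta)
  srcR <- (ct * r - st * c) / scale + cy - ty
  srcC <- (st * r + ct * c) / scale + cx - tx
  srcR <- pmin(pmax(srcR, 1), H)
  srcC <- pmin(pmax(srcC, 1), W)
  r0 <- pmin(floor(srcR), H - 1); c0 <- pmin(floor(srcC), W - 1)
  fr <- srcR - r0; fc <- srcC - c0
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    i00 <- m[cbind(as.vector(r0), as.vector(c0))]
    i10 <- m[cbind(as.vector(r0 + 1), as.vector(c0))]
    i01 <- m[cbind(as.vector(r0), as.vector(c0 + 1))]
    i11 <- m[cbind(as.vector(r0 + 1), as.vector(c0 + 1))]
    v <- i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
      i01 * (1 - fr) * fc + i11 * fr * fc
    out[, , ch] <- matrix(v, H, W)
  }
  out
}

gaussianBlur <- function(img, sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  d <- dim(img)
  # separable: vertical then horizontal depthwise pass with zero padding
  kv <- array(rep(k, each = 1, times = d[3]), c(2L * radius + 1L, 1L, d[3]))
  kh <- array(rep(k, each = 1, times = d[3]), c(1L, 2L * radius + 1L, d[3]))
  v <- dwconvForward(padArray(img, c(radius, radius, 0L, 0L)), kv, 1L, "valid")
  dwconvForward(padArray(v, c(0L, 0L, radius, radius)), kh, 1L, "valid")
}

#' Randomly augment one image
#'
#' Applies (in order) random rotation, scale and translation as one affine
#' warp, optional horizontal flip, Gaussian noise and/or blur, then a random
#' crop to `cfg$cropSize`.  With all magnitudes zero and crop equal to the
#' source size the transform is the identity.  Deterministic under `seed`.
#'
#' @param img `H x W x 3` array on the \[0, 255\] scale.
#' @param cfg From [augmentConfig()].
#' @param seed Per-call integer seed.
#' @return Augmented `cropSize x cropSize x 3` array.
#' @export
augmentImage <- function(img, cfg, seed = 1L) {
  d <- dim(img)
  if (cfg$cropSize > min(d[1:2]))
    stop("crop size exceeds the image size")
  withr::with_seed(seed, {
    theta <- stats::runif(1, -1, 1) * cfg$rotationDeg * pi / 180
    scale <- 1 + stats::runif(1, -1, 1) * cfg$scaleFrac
    tx <- stats::runif(1, -1, 1) * cfg$translateFrac * d[2]
    ty <- stats::runif(1, -1, 1) * cfg$translateFrac * d[1]
    if (theta != 0 || scale != 1 || tx != 0 || ty != 0)
      img <- affineSample(img, theta, scale, tx, ty)
    if (cfg$flip && stats::runif(1) < 0.5)
      img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    if (cfg$blurSigma > 0) img <- gaussianBlur(img, cfg$blurSigma)
    if (cfg$noiseSd > 0)
      img <- pmin(pmax(img + array(stats::rnorm(length(img), 0, cfg$noiseSd),
                                   dim(img)), 0), 255)
    maxR <- dim(img)[1] - cfg$cropSize
    maxC <- dim(img)[2] - cfg$cropSize
    r0 <- if (maxR > 0) sample.int(maxR + 1L, 1L) - 1L else 0L
    c0 <- if (maxC > 0) sample.int(maxC + 1L, 1L) - 1L else 0L
    img[r0 + seq_len(cfg$cropSize), c0 + seq_len(cfg$cropSize), ,
        drop = FALSE]
  })
}
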