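# Deterministic synthetic "leaf" image generator.  Each class is drawn as an
# elliptical leaf with a class-specific base hue, carrying a class-specific
# number and colour of circular lesion blobs, on a textured soil-like
# background, with additive Gaussian pixel noise.  The motifs make classes
# separable by simple colour statistics (a mean-colour linear probe solves
# them), which is exactly what makes small-model overfitting tests
# meaningful, while still exercising every pipeline stage on realistic
# class-per-folder PNG trees.

#' Synthetic dataset specification constructor
#'
#' @param nClasses Number of classes (>= 2).
#' @param imagesPerClass Images per class.
#' @param imageSize Square image side in pixels (>= 64, default 256).
#' @param noiseSd Additive Gaussian pixel noise standard deviation on the
#'   \[0, 1\] scale (default 8/255).
#' @param seed Integer seed; the full dataset is a pure function of the spec
#'   and seed (bit-identical regeneration).
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nClasses, imagesPerClass, imageSize = 256L,
                          noiseSd = 8 / 255, seed = 1L) {
  new("SyntheticSpec", nClasses = as.integer(nClasses),
      imagesPerClass = as.integer(imagesPerClass),
      imageSize = as.integer(imageSize), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

# Per-class motif parameters: evenly spaced leaf hues, lesion count growing
# with class id, lesion hue offset by a half-turn from the leaf hue.
classMotif <- function(classId, nClasses) {
  hue <- (classId - 1) / nClasses
  list(
    leafHue = hue,
    lesionHue = (hue + 0.5) %% 1,
    lesions = 1L + (classId - 1L) %% 4L
  )
}

hueColor <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h, s, v))) / 255
}

# Draw one image as an H x W x 3 array in [0, 1].  Consumes the current RNG
# stream; callers wrap the whole dataset in a single seeded block.
drawLeafImage <- function(motif, size, noiseSd) {
  x <- matrix(rep((seq_len(size) - 0.5) / size, each = size), size, size)
  y <- matrix(rep((seq_len(size) - 0.5) / size, times = size), size, size)

  img <- array(0, c(size, size, 3))
  soil <- hueColor(0.09, 0.45, 0.45)
  texture <- matrix(stats::rnorm(size * size, 0, 0.03), size, size)
  for (c in 1:3) img[, , c] <- soil[c] + texture

  # leaf ellipse with jittered pose
  cx <- 0.5 + stats::runif(1, -0.05, 0.05)
  cy <- 0.5 + stats::runif(1, -0.05, 0.05)
  a <- stats::runif(1, 0.30, 0.38)
  b <- stats::runif(1, 0.18, 0.26)
  th <- stats::runif(1, 0, pi)
  xr <- (x - cx) * cos(th) + (y - cy) * sin(th)
  yr <- -(x - cx) * sin(th) + (y - cy) * cos(th)
  leaf <- (xr / a)^2 + (yr / b)^2 <= 1
  leafCol <- hueColor(motif$leafHue,
                      stats::runif(1, 0.55, 0.75),
                      stats::runif(1, 0.55, 0.8))
  for (c in 1:3) {
    ch <- img[, , c]
    ch[leaf] <- leafCol[c]
    img[, , c] <- ch
  }

  # class-specific lesion blobs inside the leaf
  lesionCol <- hueColor(motif$lesionHue, 0.8, 0.9)
  for (k in seq_len(motif$lesions)) {
    u <- stats::runif(1, -0.6, 0.6); v <- stats::runif(1, -0.6, 0.6)
    lx <- cx + u * a * cos(th) - v * b * sin(th)
    ly <- cy + u * a * sin(th) + v * b * cos(th)
    r <- stats::runif(1, 0.03, 0.06)
    blob <- ((x - lx)^2 + (y - ly)^2 <= r^2) & leaf
    for (c in 1:3) {
      ch <- img[, , c]
      ch[blob] <- lesionCol[c]
      img[, , c] <- ch
    }
  }

  if (noiseSd > 0) img <- img + array(stats::rnorm(length(img), 0, noiseSd), dim(img))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic class-per-folder image dataset
#'
#' Writes `nClasses * imagesPerClass` PNG images into one subdirectory per
#' class under `outDir`, plus a `manifest.csv` of (path, label) rows.  The
#' result is bit-identical for identical spec and seed.
#'
#' @param spec A [SyntheticSpec-class].
#' @param outDir Writable output directory (created if absent).
#' @return Invisibly, the manifest data.frame with columns `path` and
#'   `label`.
#' @export
generateDataset <- function(spec, outDir) {
  validObject(spec)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outDir, 2) != 0) stop("output directory is not writable")
  paths <- character(0)
  labels <- character(0)
  withr::with_seed(spec@seed, {
    for (cls in seq_len(spec@nClasses)) {
      label <- sprintf("class_%02d", cls)
      clsDir <- file.path(outDir, label)
      dir.create(clsDir, showWarnings = FALSE)
      motif <- classMotif(cls, spec@nClasses)
      for (i in seq_len(spec@imagesPerClass)) {
        img <- drawLeafImage(motif, spec@imageSize, spec@noiseSd)
        p <- file.path(clsDir, sprintf("img_%04d.png", i))
        png::writePNG(img, p)
        paths <- c(paths, p)
        labels <- c(labels, label)
      }
    }
  })
  manifest <- data.frame(path = paths, label = labels,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
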