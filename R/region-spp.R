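# Region pooling and spatial pyramid pooling: the stage that turns a backbone
# feature map (h x w x C) into the P x C graph-node matrix.  The map is
# bilinearly upsampled to H x W, cut into a g x g grid of non-overlapping
# tiles (each averaged to a C-vector), and the g x g grid of tile descriptors
# is pooled at two bin resolutions i x i and j x j; the i^2 + j^2 pooled
# vectors, concatenated row-major with level i first, are the node features.
# With average pooling every step is linear, so the whole stage collapses to a
# single sparse P x (h*w) operator per channel (used by the trainable
# network); max pooling is supported stepwise.

#' Region/pyramid configuration constructor
#'
#' @param upsampleSize Upsampled square side H (default 16).
#' @param grid Region grid side g (default 4, i.e. 16 regions).
#' @param levels Pyramid bin resolutions `c(i, j)` (default `c(2, 3)`,
#'   giving P = 13 nodes).
#' @param poolMode `"average"` (default) or `"max"`.
#' @return A [RegionConfig-class].
#' @export
regionConfig <- function(upsampleSize = 16L, grid = 4L, levels = c(2L, 3L),
                         poolMode = c("average", "max")) {
  new("RegionConfig", upsampleSize = as.integer(upsampleSize),
      grid = as.integer(grid), levels = as.integer(levels),
      poolMode = match.arg(poolMode))
}

#' Number of graph nodes implied by a region configuration
#'
#' @param cfg A [RegionConfig-class].
#' @return Integer P = i^2 + j^2.
#' @export
nodeCount <- function(cfg) {
  sum(as.integer(cfg@levels)^2L)
}

# Bilinear interpolation weights from n source to m target samples along one
# axis, half-pixel-center convention (no corner alignment): target t samples
# source coordinate (t + 0.5) * n/m - 0.5, clamped to the valid range.
bilinearWeights <- function(n, m) {
  W <- matrix(0, m, n)
  src <- (seq_len(m) - 0.5) * n / m - 0.5
  src <- pmin(pmax(src, 0), n - 1)
  lo <- pmin(floor(src), n - 1)
  hi <- pmin(lo + 1, n - 1)
  frac <- src - lo
  for (t in seq_len(m)) {
    W[t, lo[t] + 1] <- W[t, lo[t] + 1] + (1 - frac[t])
    W[t, hi[t] + 1] <- W[t, hi[t] + 1] + frac[t]
  }
  W
}

#' Bilinearly upsample a feature map
#'
#' @param fm Numeric `h x w x C` array.
#' @param target Target spatial size, `c(H, W)` or a scalar for square
#'   output; must be at least the source size.
#' @return `H x W x C` array; channels are interpolated independently.
#' @export
upsampleMap <- function(fm, target) {
  stopifnot(length(dim(fm)) == 3L)
  if (length(target) == 1L) target <- c(target, target)
  d <- dim(fm)
  if (any(target < d[1:2]))
    stop("target size must be at least the source size")
  if (all(target == d[1:2])) return(fm)
  By <- bilinearWeights(d[1], target[1])
  Bx <- bilinearWeights(d[2], target[2])
  out <- array(0, c(target, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- By %*% fm[, , c] %*% t(Bx)
  out
}

#' Partition a feature map into a grid of region descriptors
#'
#' Cuts an `H x W x C` map into `g * g` non-overlapping `(H/g) x (W/g)` tiles
#' and averages each tile spatially into one C-vector.
#'
#' @param fm Numeric `H x W x C` array with both spatial sizes divisible by
#'   `g` (no implicit padding).
#' @param g Region grid side.
#' @return A `g x g x C` array of region descriptors; `regionMatrix()` gives
#'   the row-major `g^2 x C` matrix view.
#' @export
partitionRegions <- function(fm, g) {
  d <- dim(fm)
  if (d[1] %% g != 0L || d[2] %% g != 0L)
    stop("feature map size must be divisible by the region grid (no padding)")
  poolForward(fm, c(d[1] %/% g, d[2] %/% g), d[1] %/% g, "valid", "avg")
}

#' Row-major matrix view of a region grid
#'
#' @param grid A `g x g x C` region descriptor array.
#' @return `g^2 x C` matrix, tiles ordered row by row.
#' @export
regionMatrix <- function(grid) {
  d <- dim(grid)
  m <- matrix(0, d[1] * d[2], d[3])
  for (c in seq_len(d[3])) m[, c] <- as.numeric(t(grid[, , c]))
  m
}

# 0-based adaptive bin boundaries: bin b of n over size S spans
# [floor(b*S/n), ceil((b+1)*S/n))
adaptiveBins <- function(S, n) {
  lapply(seq_len(n) - 1L, function(b) {
    lo <- floor(b * S / n)
    hi <- ceiling((b + 1) * S / n)
    seq.int(lo + 1L, hi)
  })
}

#' Spatial pyramid pooling of a region grid
#'
#' Pools the `g x g` grid of region descriptors adaptively at the two bin
#' resolutions of `cfg@levels` and concatenates the pooled vectors row-major,
#' first level first.
#'
#' @param grid `g x g x C` region descriptor array.
#' @param levels Integer pair of bin resolutions, each at most `g`.
#' @param poolMode `"average"` or `"max"`.
#' @return A [NodeFeatures-class] with P = i^2 + j^2 rows.
#' @export
pyramidPool <- function(grid, levels = c(2L, 3L), poolMode = "average") {
  d <- dim(grid)
  if (any(levels > d[1:2])) stop("pyramid level exceeds the region grid")
  rows <- list()
  for (n in levels) {
    binsR <- adaptiveBins(d[1], n)
    binsC <- adaptiveBins(d[2], n)
    for (r in seq_len(n)) {
      for (cc in seq_len(n)) {
        blk <- grid[binsR[[r]], binsC[[cc]], , drop = FALSE]
        v <- if (poolMode == "max") apply(blk, 3, max) else apply(blk, 3, mean)
        rows[[length(rows) + 1L]] <- v
      }
    }
  }
  new("NodeFeatures", values = do.call(rbind, rows))
}

#' Node features from a backbone feature map
#'
#' Runs the full upsample -> region grid -> spatial pyramid stage.
#'
#' @param fm `h x w x C` backbone feature map.
#' @param cfg A [RegionConfig-class].
#' @param regionsOnly If `TRUE`, bypass the pyramid: the nodes are the g^2
#'   region descriptors themselves (the region-pooling-only ablation).
#' @return A [NodeFeatures-class].
#' @export
spatialNodes <- function(fm, cfg, regionsOnly = FALSE) {
  up <- upsampleMap(fm, cfg@upsampleSize)
  grid <- partitionRegions(up, cfg@grid)
  if (regionsOnly) return(new("NodeFeatures", values = regionMatrix(grid)))
  pyramidPool(grid, cfg@levels, cfg@poolMode)
}

## ---- linear-operator form used by the trainable network ----

# Sparse omega x (H*W) row-major tile-averaging operator (column-major
# flattening of the H x W map in the columns).
regionOperator <- function(H, W, g) {
  th <- H %/% g; tw <- W %/% g
  i <- integer(0); j <- integer(0)
  for (r in seq_len(g)) {
    for (cc in seq_len(g)) {
      tile <- (r - 1L) * g + cc          # row-major tile id
      rows <- (r - 1L) * th + seq_len(th)
      cols <- (cc - 1L) * tw + seq_len(tw)
      cells <- as.integer(outer(rows, (cols - 1L) * H, "+"))
      i <- c(i, rep.int(tile, length(cells)))
      j <- c(j, cells)
    }
  }
  Matrix::sparseMatrix(i = i, j = j, x = 1 / (th * tw), dims = c(g * g, H * W))
}

# P x omega adaptive average-pyramid operator over the row-major g x g grid.
pyramidOperator <- function(g, levels) {
  i <- integer(0); j <- integer(0); x <- numeric(0)
  node <- 0L
  for (n in levels) {
    binsR <- adaptiveBins(g, n)
    binsC <- adaptiveBins(g, n)
    for (r in seq_len(n)) {
      for (cc in seq_len(n)) {
        node <- node + 1L
        cells <- as.integer(outer((binsR[[r]] - 1L) * g, binsC[[cc]], "+"))
        i <- c(i, rep.int(node, length(cells)))
        j <- c(j, cells)
        x <- c(x, rep.int(1 / length(cells), length(cells)))
      }
    }
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(node, g * g))
}

# Combined operator: flattened (column-major) h x w map -> node features.
# Returns the pieces so max-mode pooling and ablations can reuse the region
# stage.
nodePipelineOperators <- function(cfg, sourceSize) {
  H <- cfg@upsampleSize
  By <- bilinearWeights(sourceSize[1], H)
  Bx <- bilinearWeights(sourceSize[2], H)
  B <- Matrix::Matrix(kronecker(Bx, By), sparse = TRUE)  # vec(ByXBx') = (Bx (x) By) vec(X)
  RB <- regionOperator(H, H, cfg@grid) %*% B             # omega x (h*w)
  S <- if (cfg@poolMode == "average") pyramidOperator(cfg@grid, cfg@levels) else NULL
  list(RB = RB, S = S)
}
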