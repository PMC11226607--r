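# Minimal layer-graph machinery used by the backbone adapters: a directed
# acyclic graph of tensor ops with shape inference, parameter accounting and a
# numeric forward pass (im2col convolutions over BLAS).  Layers are appended in
# topological order by the architecture builders, so evaluation is a single
# in-order sweep.

layerGraph <- function() {
  env <- new.env(parent = emptyenv())
  env$layers <- list()
  env$n <- 0L
  env
}

addLayer <- function(g, op, inputs, ...) {
  g$n <- g$n + 1L
  id <- sprintf("%s_%03d", op, g$n)
  g$layers[[id]] <- c(list(id = id, op = op, inputs = inputs), list(...))
  id
}

#' @importFrom stats setNames
layerShapes <- function(layers, inputShape) {
  shapes <- list(input = inputShape)
  convOut <- function(n, k, s, padding) {
    if (padding == "same") ceiling(n / s) else floor((n - k) / s) + 1L
  }
  for (ly in layers) {
    ins <- lapply(ly$inputs, function(i) shapes[[i]])
    s1 <- ins[[1]]
    shapes[[ly$id]] <- switch(ly$op,
      conv = c(convOut(s1[1], ly$k[1], ly$stride, ly$padding),
               convOut(s1[2], ly$k[2], ly$stride, ly$padding), ly$filters),
      dwconv = c(convOut(s1[1], ly$k[1], ly$stride, ly$padding),
                 convOut(s1[2], ly$k[2], ly$stride, ly$padding), s1[3]),
      sepconv = c(convOut(s1[1], ly$k[1], ly$stride, ly$padding),
                  convOut(s1[2], ly$k[2], ly$stride, ly$padding), ly$filters),
      maxpool = ,
      avgpool = c(convOut(s1[1], ly$k[1], ly$stride, ly$padding),
                  convOut(s1[2], ly$k[2], ly$stride, ly$padding), s1[3]),
      zeropad = c(s1[1] + sum(ly$pad[1:2]), s1[2] + sum(ly$pad[3:4]), s1[3]),
      bn = s1,
      relu = s1,
      add = s1,
      concat = c(s1[1], s1[2], sum(vapply(ins, `[`, numeric(1), 3))),
      gap = c(1, 1, s1[3]),
      dense = c(1, 1, ly$units),
      stop("unknown op: ", ly$op)
    )
  }
  shapes
}

# Exact trainable + tracked-statistic parameter count per layer, given the
# inferred input channel widths.  Batch-norm contributes 4C (or 3C when the
# scale term is omitted, as some architectures do).
layerParamCounts <- function(layers, shapes) {
  counts <- numeric(length(layers))
  names(counts) <- vapply(layers, `[[`, character(1), "id")
  for (ly in layers) {
    cin <- shapes[[ly$inputs[1]]][3]
    counts[ly$id] <- switch(ly$op,
      conv = prod(ly$k) * cin * ly$filters + (if (isTRUE(ly$bias)) ly$filters else 0),
      dwconv = prod(ly$k) * cin,
      sepconv = prod(ly$k) * cin + cin * ly$filters +
        (if (isTRUE(ly$bias)) ly$filters else 0),
      bn = (if (isTRUE(ly$scale)) 4 else 3) * cin,
      dense = cin * ly$units + (if (isTRUE(ly$bias)) ly$units else 0),
      0
    )
  }
  counts
}

## ---- numeric tensor ops (H x W x C arrays) ----

padArray <- function(x, pad) {
  # pad = c(top, bottom, left, right)
  d <- dim(x)
  out <- array(0, c(d[1] + pad[1] + pad[2], d[2] + pad[3] + pad[4], d[3]))
  out[pad[1] + seq_len(d[1]), pad[3] + seq_len(d[2]), ] <- x
  out
}

# TensorFlow-style "same" padding amounts for one spatial axis
samePad <- function(n, k, s) {
  total <- max((ceiling(n / s) - 1) * s + k - n, 0)
  c(floor(total / 2), ceiling(total / 2))
}

applyPadding <- function(x, k, stride, padding) {
  if (padding == "valid") return(x)
  d <- dim(x)
  pv <- samePad(d[1], k[1], stride)
  ph <- samePad(d[2], k[2], stride)
  if (all(c(pv, ph) == 0)) x else padArray(x, c(pv, ph))
}

im2col <- function(x, kh, kw, stride) {
  d <- dim(x)
  oh <- (d[1] - kh) %/% stride + 1L
  ow <- (d[2] - kw) %/% stride + 1L
  C <- d[3]
  rows <- (seq_len(oh) - 1L) * stride
  cols <- (seq_len(ow) - 1L) * stride
  out <- matrix(0, oh * ow, kh * kw * C)
  k <- 0L
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      k <- k + 1L
      blk <- x[rows + di, cols + dj, , drop = FALSE]
      out[, ((k - 1L) * C + 1L):(k * C)] <- matrix(blk, oh * ow, C)
    }
  }
  attr(out, "outdim") <- c(oh, ow)
  out
}

# scatter-add transpose of im2col (used by backprop through stride-1 convs)
col2im <- function(cols, indim, kh, kw, stride) {
  oh <- (indim[1] - kh) %/% stride + 1L
  ow <- (indim[2] - kw) %/% stride + 1L
  C <- indim[3]
  x <- array(0, indim)
  rows <- (seq_len(oh) - 1L) * stride
  cols_ <- (seq_len(ow) - 1L) * stride
  k <- 0L
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      k <- k + 1L
      blk <- array(cols[, ((k - 1L) * C + 1L):(k * C)], c(oh, ow, C))
      x[rows + di, cols_ + dj, ] <- x[rows + di, cols_ + dj, , drop = FALSE] + blk
    }
  }
  x
}

convForward <- function(x, W, b, k, stride, padding) {
  x <- applyPadding(x, k, stride, padding)
  cols <- im2col(x, k[1], k[2], stride)
  od <- attr(cols, "outdim")
  out <- cols %*% W
  if (!is.null(b)) out <- sweep(out, 2, b, "+")
  array(out, c(od, ncol(W)))
}

dwconvForward <- function(x, W, stride, padding) {
  # W: kh x kw x C
  k <- dim(W)[1:2]
  x <- applyPadding(x, k, stride, padding)
  d <- dim(x)
  oh <- (d[1] - k[1]) %/% stride + 1L
  ow <- (d[2] - k[2]) %/% stride + 1L
  rows <- (seq_len(oh) - 1L) * stride
  cols <- (seq_len(ow) - 1L) * stride
  out <- array(0, c(oh, ow, d[3]))
  for (dj in seq_len(k[2])) {
    for (di in seq_len(k[1])) {
      blk <- x[rows + di, cols + dj, , drop = FALSE]
      out <- out + sweep(blk, 3, W[di, dj, ], "*")
    }
  }
  out
}

poolForward <- function(x, k, stride, padding, mode) {
  xp <- applyPadding(x, k, stride, padding)
  d <- dim(xp)
  oh <- (d[1] - k[1]) %/% stride + 1L
  ow <- (d[2] - k[2]) %/% stride + 1L
  rows <- (seq_len(oh) - 1L) * stride
  cols <- (seq_len(ow) - 1L) * stride
  out <- if (mode == "max") array(-Inf, c(oh, ow, d[3])) else array(0, c(oh, ow, d[3]))
  for (dj in seq_len(k[2])) {
    for (di in seq_len(k[1])) {
      blk <- xp[rows + di, cols + dj, , drop = FALSE]
      out <- if (mode == "max") pmax(out, blk) else out + blk
    }
  }
  if (mode == "avg") out <- out / prod(k)
  out
}

glorotUniform <- function(fanIn, fanOut, n) {
  lim <- sqrt(6 / (fanIn + fanOut))
  stats::runif(n, -lim, lim)
}

# Materialize seeded random weights for every parameterized layer.
initGraphParams <- function(layers, shapes, seed) {
  params <- list()
  withr::with_seed(seed, {
    for (ly in layers) {
      cin <- shapes[[ly$inputs[1]]][3]
      params[[ly$id]] <- switch(ly$op,
        conv = {
          fi <- prod(ly$k) * cin
          list(W = matrix(glorotUniform(fi, ly$filters, fi * ly$filters),
                          fi, ly$filters),
               b = if (isTRUE(ly$bias)) numeric(ly$filters) else NULL)
        },
        dwconv = list(W = array(glorotUniform(prod(ly$k), 1, prod(ly$k) * cin),
                                c(ly$k, cin))),
        sepconv = {
          fi <- cin
          list(Wd = array(glorotUniform(prod(ly$k), 1, prod(ly$k) * cin),
                          c(ly$k, cin)),
               Wp = matrix(glorotUniform(cin, ly$filters, cin * ly$filters),
                           cin, ly$filters),
               b = if (isTRUE(ly$bias)) numeric(ly$filters) else NULL)
        },
        bn = list(gamma = if (isTRUE(ly$scale)) rep(1, cin) else NULL,
                  beta = numeric(cin), mean = numeric(cin), var = rep(1, cin)),
        dense = list(W = matrix(glorotUniform(cin, ly$units, cin * ly$units),
                                cin, ly$units),
                     b = if (isTRUE(ly$bias)) numeric(ly$units) else NULL),
        NULL
      )
    }
  })
  params
}

bnForward <- function(x, p, eps = 1e-3) {
  d <- dim(x)
  xm <- matrix(x, prod(d[1:2]), d[3])
  xm <- sweep(xm, 2, p$mean, "-")
  xm <- sweep(xm, 2, sqrt(p$var + eps), "/")
  if (!is.null(p$gamma)) xm <- sweep(xm, 2, p$gamma, "*")
  xm <- sweep(xm, 2, p$beta, "+")
  array(xm, d)
}

# Forward pass of a layer graph on a single H x W x C image.
graphForward <- function(layers, params, x, stopAt = NULL) {
  vals <- list(input = x)
  for (ly in layers) {
    ins <- lapply(ly$inputs, function(i) vals[[i]])
    v <- ins[[1]]
    p <- params[[ly$id]]
    vals[[ly$id]] <- switch(ly$op,
      conv = convForward(v, p$W, p$b, ly$k, ly$stride, ly$padding),
      dwconv = dwconvForward(v, p$W, ly$stride, ly$padding),
      sepconv = {
        dv <- dwconvForward(v, p$Wd, ly$stride, ly$padding)
        convForward(dv, p$Wp, p$b, c(1L, 1L), 1L, "valid")
      },
      bn = bnForward(v, p),
      relu = pmax(v, 0),
      maxpool = poolForward(v, ly$k, ly$stride, ly$padding, "max"),
      avgpool = poolForward(v, ly$k, ly$stride, ly$padding, "avg"),
      zeropad = padArray(v, ly$pad),
      add = Reduce(`+`, ins),
      concat = {
        d <- dim(v)
        array(unlist(lapply(ins, as.numeric), use.names = FALSE),
              c(d[1], d[2], sum(vapply(ins, function(a) dim(a)[3], numeric(1)))))
      },
      gap = array(apply(v, 3, mean), c(1, 1, dim(v)[3])),
      dense = {
        out <- as.numeric(matrix(v, 1) %*% p$W)
        if (!is.null(p$b)) out <- out + p$b
        array(out, c(1, 1, length(out)))
      },
      stop("unknown op: ", ly$op)
    )
    if (!is.null(stopAt) && ly$id == stopAt) return(vals[[ly$id]])
  }
  vals[[layers[[length(layers)]]$id]]
}
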