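# Backbone adapters.  Four standard ImageNet architectures are encoded layer
# by layer, following the reference (Keras Applications) layouts so that
# parameter accounting is exact; a fifth, deliberately small "tiny" backbone
# exists so that the full pipeline trains in seconds on a CPU.

## ---- architecture builders ----

# conv + batch-norm + ReLU triplet shared by several builders
convBnRelu <- function(g, inp, filters, k, stride = 1L, padding = "same",
                       bias = FALSE, scale = TRUE) {
  id <- addLayer(g, "conv", inp, filters = filters, k = k, stride = stride,
                 padding = padding, bias = bias)
  id <- addLayer(g, "bn", id, scale = scale)
  addLayer(g, "relu", id)
}

resnet50Graph <- function(numClasses = 1000L, includeTop = TRUE) {
  g <- layerGraph()
  x <- addLayer(g, "zeropad", "input", pad = c(3L, 3L, 3L, 3L))
  x <- addLayer(g, "conv", x, filters = 64L, k = c(7L, 7L), stride = 2L,
                padding = "valid", bias = TRUE)
  x <- addLayer(g, "bn", x, scale = TRUE)
  x <- addLayer(g, "relu", x)
  x <- addLayer(g, "zeropad", x, pad = c(1L, 1L, 1L, 1L))
  x <- addLayer(g, "maxpool", x, k = c(3L, 3L), stride = 2L, padding = "valid")

  bottleneck <- function(x, f, stride, shortcutConv) {
    sc <- x
    if (shortcutConv) {
      sc <- addLayer(g, "conv", x, filters = f[3], k = c(1L, 1L),
                     stride = stride, padding = "valid", bias = TRUE)
      sc <- addLayer(g, "bn", sc, scale = TRUE)
    }
    y <- addLayer(g, "conv", x, filters = f[1], k = c(1L, 1L), stride = stride,
                  padding = "valid", bias = TRUE)
    y <- addLayer(g, "bn", y, scale = TRUE)
    y <- addLayer(g, "relu", y)
    y <- addLayer(g, "conv", y, filters = f[2], k = c(3L, 3L), stride = 1L,
                  padding = "same", bias = TRUE)
    y <- addLayer(g, "bn", y, scale = TRUE)
    y <- addLayer(g, "relu", y)
    y <- addLayer(g, "conv", y, filters = f[3], k = c(1L, 1L), stride = 1L,
                  padding = "valid", bias = TRUE)
    y <- addLayer(g, "bn", y, scale = TRUE)
    y <- addLayer(g, "add", c(y, sc))
    addLayer(g, "relu", y)
  }
  stages <- list(list(f = c(64L, 64L, 256L), n = 3L, s = 1L),
                 list(f = c(128L, 128L, 512L), n = 4L, s = 2L),
                 list(f = c(256L, 256L, 1024L), n = 6L, s = 2L),
                 list(f = c(512L, 512L, 2048L), n = 3L, s = 2L))
  for (st in stages) {
    x <- bottleneck(x, st$f, st$s, TRUE)
    for (i in seq_len(st$n - 1L)) x <- bottleneck(x, st$f, 1L, FALSE)
  }
  feature <- x
  if (includeTop) {
    x <- addLayer(g, "gap", x)
    x <- addLayer(g, "dense", x, units = numClasses, bias = TRUE)
  }
  list(layers = g$layers, output = x, feature = feature)
}

xceptionGraph <- function(numClasses = 1000L, includeTop = TRUE) {
  g <- layerGraph()
  x <- convBnRelu(g, "input", 32L, c(3L, 3L), stride = 2L, padding = "valid")
  x <- convBnRelu(g, x, 64L, c(3L, 3L), padding = "valid")

  sepBn <- function(x, filters) {
    id <- addLayer(g, "sepconv", x, filters = filters, k = c(3L, 3L),
                   stride = 1L, padding = "same", bias = FALSE)
    addLayer(g, "bn", id, scale = TRUE)
  }
  downBlock <- function(x, filters, leadingRelu) {
    sc <- addLayer(g, "conv", x, filters = filters, k = c(1L, 1L), stride = 2L,
                   padding = "same", bias = FALSE)
    sc <- addLayer(g, "bn", sc, scale = TRUE)
    y <- if (leadingRelu) addLayer(g, "relu", x) else x
    y <- sepBn(y, filters)
    y <- addLayer(g, "relu", y)
    y <- sepBn(y, filters)
    y <- addLayer(g, "maxpool", y, k = c(3L, 3L), stride = 2L, padding = "same")
    addLayer(g, "add", c(y, sc))
  }
  x <- downBlock(x, 128L, leadingRelu = FALSE)
  x <- downBlock(x, 256L, leadingRelu = TRUE)
  x <- downBlock(x, 728L, leadingRelu = TRUE)
  for (i in seq_len(8L)) {               # middle flow
    y <- x
    for (j in seq_len(3L)) {
      y <- addLayer(g, "relu", y)
      y <- sepBn(y, 728L)
    }
    x <- addLayer(g, "add", c(y, x))
  }
  sc <- addLayer(g, "conv", x, filters = 1024L, k = c(1L, 1L), stride = 2L,
                 padding = "same", bias = FALSE)
  sc <- addLayer(g, "bn", sc, scale = TRUE)
  y <- addLayer(g, "relu", x)
  y <- sepBn(y, 728L)
  y <- addLayer(g, "relu", y)
  y <- sepBn(y, 1024L)
  y <- addLayer(g, "maxpool", y, k = c(3L, 3L), stride = 2L, padding = "same")
  x <- addLayer(g, "add", c(y, sc))
  x <- sepBn(x, 1536L)
  x <- addLayer(g, "relu", x)
  x <- sepBn(x, 2048L)
  x <- addLayer(g, "relu", x)
  feature <- x
  if (includeTop) {
    x <- addLayer(g, "gap", x)
    x <- addLayer(g, "dense", x, units = numClasses, bias = TRUE)
  }
  list(layers = g$layers, output = x, feature = feature)
}

mobileNetV2Graph <- function(numClasses = 1000L, includeTop = TRUE) {
  g <- layerGraph()
  x <- addLayer(g, "conv", "input", filters = 32L, k = c(3L, 3L), stride = 2L,
                padding = "same", bias = FALSE)
  x <- addLayer(g, "bn", x, scale = TRUE)
  x <- addLayer(g, "relu", x)

  cin <- 32L
  invResidual <- function(x, t, cout, stride) {
    y <- x
    if (t != 1L) {
      y <- addLayer(g, "conv", y, filters = t * cin, k = c(1L, 1L), stride = 1L,
                    padding = "same", bias = FALSE)
      y <- addLayer(g, "bn", y, scale = TRUE)
      y <- addLayer(g, "relu", y)
    }
    y <- addLayer(g, "dwconv", y, k = c(3L, 3L), stride = stride,
                  padding = "same")
    y <- addLayer(g, "bn", y, scale = TRUE)
    y <- addLayer(g, "relu", y)
    y <- addLayer(g, "conv", y, filters = cout, k = c(1L, 1L), stride = 1L,
                  padding = "same", bias = FALSE)
    y <- addLayer(g, "bn", y, scale = TRUE)
    if (stride == 1L && cin == cout) y <- addLayer(g, "add", c(y, x))
    cin <<- cout
    y
  }
  blocks <- list(c(1L, 16L, 1L, 1L), c(6L, 24L, 2L, 2L), c(6L, 32L, 3L, 2L),
                 c(6L, 64L, 4L, 2L), c(6L, 96L, 3L, 1L), c(6L, 160L, 3L, 2L),
                 c(6L, 320L, 1L, 1L))
  for (b in blocks) {
    strides <- c(b[4], rep(1L, b[3] - 1L))
    for (s in strides) x <- invResidual(x, b[1], b[2], s)
  }
  x <- addLayer(g, "conv", x, filters = 1280L, k = c(1L, 1L), stride = 1L,
                padding = "same", bias = FALSE)
  x <- addLayer(g, "bn", x, scale = TRUE)
  x <- addLayer(g, "relu", x)
  feature <- x
  if (includeTop) {
    x <- addLayer(g, "gap", x)
    x <- addLayer(g, "dense", x, units = numClasses, bias = TRUE)
  }
  list(layers = g$layers, output = x, feature = feature)
}

inceptionV3Graph <- function(numClasses = 1000L, includeTop = TRUE) {
  g <- layerGraph()
  cb <- function(inp, filters, k, stride = 1L, padding = "same") {
    convBnRelu(g, inp, filters, k, stride, padding, bias = FALSE, scale = FALSE)
  }
  x <- cb("input", 32L, c(3L, 3L), stride = 2L, padding = "valid")
  x <- cb(x, 32L, c(3L, 3L), padding = "valid")
  x <- cb(x, 64L, c(3L, 3L))
  x <- addLayer(g, "maxpool", x, k = c(3L, 3L), stride = 2L, padding = "valid")
  x <- cb(x, 80L, c(1L, 1L), padding = "valid")
  x <- cb(x, 192L, c(3L, 3L), padding = "valid")
  x <- addLayer(g, "maxpool", x, k = c(3L, 3L), stride = 2L, padding = "valid")

  poolConv <- function(x, filters) {
    p <- addLayer(g, "avgpool", x, k = c(3L, 3L), stride = 1L, padding = "same")
    cb(p, filters, c(1L, 1L))
  }
  mixedA <- function(x, poolFilters) {   # 35x35 modules
    b1 <- cb(x, 64L, c(1L, 1L))
    b5 <- cb(cb(x, 48L, c(1L, 1L)), 64L, c(5L, 5L))
    b3 <- cb(cb(cb(x, 64L, c(1L, 1L)), 96L, c(3L, 3L)), 96L, c(3L, 3L))
    addLayer(g, "concat", c(b1, b5, b3, poolConv(x, poolFilters)))
  }
  x <- mixedA(x, 32L)
  x <- mixedA(x, 64L)
  x <- mixedA(x, 64L)
  # mixed3: grid reduction to 17x17
  b3 <- cb(x, 384L, c(3L, 3L), stride = 2L, padding = "valid")
  bd <- cb(cb(cb(x, 64L, c(1L, 1L)), 96L, c(3L, 3L)), 96L, c(3L, 3L),
           stride = 2L, padding = "valid")
  mp <- addLayer(g, "maxpool", x, k = c(3L, 3L), stride = 2L, padding = "valid")
  x <- addLayer(g, "concat", c(b3, bd, mp))
  mixedB <- function(x, w) {             # 17x17 modules, factorized 7x7
    b1 <- cb(x, 192L, c(1L, 1L))
    b7 <- cb(cb(cb(x, w, c(1L, 1L)), w, c(1L, 7L)), 192L, c(7L, 1L))
    bd <- cb(cb(cb(cb(cb(x, w, c(1L, 1L)), w, c(7L, 1L)), w, c(1L, 7L)),
                w, c(7L, 1L)), 192L, c(1L, 7L))
    addLayer(g, "concat", c(b1, b7, bd, poolConv(x, 192L)))
  }
  x <- mixedB(x, 128L)
  x <- mixedB(x, 160L)
  x <- mixedB(x, 160L)
  x <- mixedB(x, 192L)
  # mixed8: grid reduction to 8x8
  b3 <- cb(cb(x, 192L, c(1L, 1L)), 320L, c(3L, 3L), stride = 2L,
           padding = "valid")
  b7 <- cb(cb(cb(cb(x, 192L, c(1L, 1L)), 192L, c(1L, 7L)), 192L, c(7L, 1L)),
           192L, c(3L, 3L), stride = 2L, padding = "valid")
  mp <- addLayer(g, "maxpool", x, k = c(3L, 3L), stride = 2L, padding = "valid")
  x <- addLayer(g, "concat", c(b3, b7, mp))
  mixedC <- function(x) {                # 8x8 modules with split branches
    b1 <- cb(x, 320L, c(1L, 1L))
    s <- cb(x, 384L, c(1L, 1L))
    b3 <- addLayer(g, "concat", c(cb(s, 384L, c(1L, 3L)),
                                  cb(s, 384L, c(3L, 1L))))
    d <- cb(cb(x, 448L, c(1L, 1L)), 384L, c(3L, 3L))
    bd <- addLayer(g, "concat", c(cb(d, 384L, c(1L, 3L)),
                                  cb(d, 384L, c(3L, 1L))))
    addLayer(g, "concat", c(b1, b3, bd, poolConv(x, 192L)))
  }
  x <- mixedC(x)
  x <- mixedC(x)
  feature <- x
  if (includeTop) {
    x <- addLayer(g, "gap", x)
    x <- addLayer(g, "dense", x, units = numClasses, bias = TRUE)
  }
  list(layers = g$layers, output = x, feature = feature)
}

## ---- registry and public surface ----

backboneBuilders <- list(
  xception = xceptionGraph,
  resnet50 = resnet50Graph,
  inceptionv3 = inceptionV3Graph,
  mobilenetv2 = mobileNetV2Graph
)

backboneChannels <- c(xception = 2048L, resnet50 = 2048L,
                      inceptionv3 = 2048L, mobilenetv2 = 1280L, tiny = 32L)

#' List available backbone feature extractors
#'
#' @return A data.frame with one row per registered backbone giving its output
#'   channel width `C` and the spatial grid of its final feature map on the
#'   default 224x224 input (64x64 for the tiny test backbone).
#' @export
listBackbones <- function() {
  nm <- c(names(backboneBuilders), "tiny")
  grid <- vapply(nm, function(n) {
    if (n == "tiny") return(4L)
    b <- backboneBuilders[[n]](includeTop = FALSE)
    as.integer(layerShapes(b$layers, c(224, 224, 3))[[b$feature]][1])
  }, integer(1))
  data.frame(name = nm, channels = unname(backboneChannels[nm]),
             baseGrid = unname(grid), row.names = NULL)
}

#' Load a backbone feature extractor
#'
#' Instantiates one of the registered convolutional architectures as a feature
#' extractor (classification top removed) or, with `includeTop = TRUE`, as the
#' full classifier used for parameter accounting.  Pretrained weights are not
#' bundled with the package: requesting them without pointing at a weights
#' source is an explicit error rather than a silent random initialization.
#'
#' @param name One of `"xception"`, `"resnet50"`, `"inceptionv3"`,
#'   `"mobilenetv2"` or `"tiny"`.
#' @param pretrained Logical; if `TRUE`, fail unless pretrained weights can be
#'   supplied (none ship with this package).
#' @param includeTop Keep the 1000-way ImageNet classification head (used for
#'   parameter accounting against published totals).
#' @param numClasses Size of the classification head when `includeTop = TRUE`.
#' @param seed Integer seed controlling the random (Glorot-uniform weight)
#'   initialization when `pretrained = FALSE`.
#' @return A [Backbone-class] object.
#' @export
loadBackbone <- function(name, pretrained = FALSE, includeTop = FALSE,
                         numClasses = 1000L, seed = 1L) {
  name <- match.arg(name, c(names(backboneBuilders), "tiny"))
  if (pretrained) {
    stop("pretrained weights for '", name, "' are not available in this ",
         "installation; pass pretrained = FALSE for a seeded random ",
         "initialization or supply weights externally")
  }
  if (name == "tiny") {
    params <- tinyBackboneInit(seed)
    return(new("Backbone", name = "tiny", layers = list(),
               params = params, channels = 32L, featureLayer = "tiny",
               includeTop = FALSE, seed = as.integer(seed)))
  }
  b <- backboneBuilders[[name]](numClasses = numClasses, includeTop = includeTop)
  shapes <- layerShapes(b$layers, c(224, 224, 3))
  params <- initGraphParams(b$layers, shapes, seed)
  new("Backbone", name = name, layers = b$layers, params = params,
      channels = backboneChannels[[name]], featureLayer = b$feature,
      includeTop = includeTop, seed = as.integer(seed))
}

#' @describeIn countParameters Exact parameter count of a backbone, including
#'   batch-normalization statistics, matching the reference implementations.
#' @export
setMethod("countParameters", "Backbone", function(object) {
  if (object@name == "tiny") {
    return(sum(vapply(unlist(object@params, recursive = FALSE),
                      length, numeric(1))))
  }
  shapes <- layerShapes(object@layers, c(224, 224, 3))
  sum(layerParamCounts(object@layers, shapes))
})

#' Parameter count in millions, rounded to one decimal
#'
#' @param object A model or backbone understood by [countParameters()].
#' @return Numeric scalar, millions of parameters at one-decimal precision.
#' @export
parameterMillions <- function(object) {
  round(countParameters(object) / 1e6, 1)
}

#' Compute the backbone feature map of an image batch
#'
#' @param object A [Backbone-class].
#' @param images A numeric array `N x H x W x 3` (batch) or `H x W x 3`
#'   (single image), already preprocessed (see [preprocessImages()]).
#' @return An `N x h x w x C` array of final convolutional activations.
#' @export
setMethod("featureMap", "Backbone", function(object, images) {
  if (length(dim(images)) == 3L) {
    images <- array(images, c(1L, dim(images)))
  }
  stopifnot(length(dim(images)) == 4L, dim(images)[4] == 3L)
  n <- dim(images)[1]
  one <- function(i) {
    img <- array(images[i, , , ], dim(images)[2:4])
    if (object@name == "tiny") {
      tinyBackboneForward(img, object@params)$out
    } else {
      graphForward(object@layers, object@params, img,
                   stopAt = object@featureLayer)
    }
  }
  first <- one(1)
  out <- array(0, c(n, dim(first)))
  out[1, , , ] <- first
  for (i in seq_len(n)[-1]) out[i, , , ] <- one(i)
  out
})

## ---- tiny backbone ----
# Three convolution blocks (3x3 stride-1 "same" convolution, ReLU, average
# pooling), channel widths 8 -> 16 -> 32, mapping 64x64x3 to 4x4x32.  It is a
# test fixture: small enough that the whole network trains in seconds, and its
# parameter count is hand-checkable: (3*3*3*8+8)+(3*3*8*16+16)+(3*3*16*32+32).

tinyBackboneSpec <- list(
  list(cin = 3L, cout = 8L, pool = 2L),
  list(cin = 8L, cout = 16L, pool = 2L),
  list(cin = 16L, cout = 32L, pool = 4L)
)

tinyBackboneInit <- function(seed) {
  withr::with_seed(seed, {
    lapply(tinyBackboneSpec, function(sp) {
      fi <- 9L * sp$cin
      list(W = matrix(glorotUniform(fi, sp$cout, fi * sp$cout), fi, sp$cout),
           b = numeric(sp$cout))
    })
  })
}

tinyBackboneForward <- function(img, params) {
  cache <- list(input = img)
  x <- img
  for (i in seq_along(tinyBackboneSpec)) {
    sp <- tinyBackboneSpec[[i]]
    xp <- padArray(x, c(1L, 1L, 1L, 1L))
    cols <- im2col(xp, 3L, 3L, 1L)
    od <- attr(cols, "outdim")
    z <- sweep(cols %*% params[[i]]$W, 2, params[[i]]$b, "+")
    a <- pmax(z, 0)
    amap <- array(a, c(od, sp$cout))
    pooled <- poolForward(amap, c(sp$pool, sp$pool), sp$pool, "valid", "avg")
    cache[[paste0("cols", i)]] <- cols
    cache[[paste0("z", i)]] <- array(z, c(od, sp$cout))
    cache[[paste0("a", i)]] <- amap
    x <- pooled
    cache[[paste0("p", i)]] <- pooled
  }
  list(out = x, cache = cache)
}

# Gradient of a scalar loss wrt tiny-backbone weights and (optionally) the
# final-conv activations, given d(loss)/d(backbone output map).
tinyBackboneBackward <- function(dOut, params, cache) {
  grads <- vector("list", 3L)
  dx <- dOut
  for (i in 3:1) {
    sp <- tinyBackboneSpec[[i]]
    amap <- cache[[paste0("a", i)]]
    # avg-pool backward: replicate / k^2
    k <- sp$pool
    da <- array(0, dim(amap))
    idx1 <- rep(seq_len(dim(dx)[1]), each = k)
    idx2 <- rep(seq_len(dim(dx)[2]), each = k)
    da <- dx[idx1, idx2, , drop = FALSE] / (k * k)
    if (i == 3L) gradsAct <- da      # pre-pool activation grad, for Grad-CAM
    dz <- da * (cache[[paste0("z", i)]] > 0)
    od <- dim(dz)
    dzm <- matrix(dz, od[1] * od[2], od[3])
    cols <- cache[[paste0("cols", i)]]
    grads[[i]] <- list(W = crossprod(cols, dzm), b = colSums(dzm))
    if (i > 1L) {
      dcols <- dzm %*% t(params[[i]]$W)
      indim <- dim(cache[[paste0("p", i - 1L)]])
      dxp <- col2im(dcols, indim + c(2L, 2L, 0L), 3L, 3L, 1L)
      dx <- dxp[2:(indim[1] + 1L), 2:(indim[2] + 1L), , drop = FALSE]
    }
  }
  list(weights = grads, lastConvAct = gradsAct)
}
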