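# Network assembly and training.  The assembled model runs
# image -> backbone map -> upsample/region grid/spatial pyramid -> GCN ->
# global average pooling over nodes -> head normalization -> dropout ->
# dense softmax.  With average pyramid pooling the node stage is a fixed
# sparse linear operator, so backpropagation through it is a transpose;
# training is plain SGD on categorical cross-entropy with a step
# learning-rate schedule.

#' Model configuration
#'
#' @param backbone Backbone name (see [listBackbones()]); the tiny backbone
#'   is the one that trains end-to-end at desk scale.
#' @param region A [RegionConfig-class] (see [regionConfig()]).
#' @param numClasses Number of output classes Y (>= 2).
#' @param gcnLayers Number of graph-convolution layers (1 or 2; default 2).
#' @param gcnFeatures Channel width of the GCN layers; default keeps the
#'   backbone channel width uniform through the module.
#' @param gcnEnabled If `FALSE`, node features bypass the GCN (ablation).
#' @param noSpp If `TRUE`, the pyramid stage is bypassed and the g^2 region
#'   descriptors are the graph nodes (ablation).
#' @param regionsOnly Convenience ablation: region pooling only, implying
#'   `noSpp = TRUE` and `gcnEnabled = FALSE`.
#' @param dropoutRate Dropout rate in the head (default 0.3).
#' @param headNorm `"layer"` (default) or `"batch"` normalization of the
#'   pooled feature vector.
#' @param seed Seed for weight initialization.
#' @return Validated configuration list.
#' @export
modelConfig <- function(backbone = "tiny", region = regionConfig(),
                        numClasses = 2L, gcnLayers = 2L, gcnFeatures = NULL,
                        gcnEnabled = TRUE, noSpp = FALSE, regionsOnly = FALSE,
                        dropoutRate = 0.3, headNorm = c("layer", "batch"),
                        seed = 1L) {
  if (numClasses < 2L) stop("numClasses must be >= 2")
  if (dropoutRate < 0 || dropoutRate >= 1) stop("dropoutRate must be in [0, 1)")
  if (!gcnLayers %in% 1:2) stop("gcnLayers must be 1 or 2")
  if (regionsOnly) { noSpp <- TRUE; gcnEnabled <- FALSE }
  validObject(region)
  list(backbone = backbone, region = region,
       numClasses = as.integer(numClasses), gcnLayers = as.integer(gcnLayers),
       gcnFeatures = gcnFeatures, gcnEnabled = isTRUE(gcnEnabled),
       noSpp = isTRUE(noSpp), regionsOnly = isTRUE(regionsOnly),
       dropoutRate = dropoutRate, headNorm = match.arg(headNorm),
       seed = as.integer(seed))
}

pyramidBinCells <- function(g, levels) {
  cells <- list()
  for (n in levels) {
    binsR <- adaptiveBins(g, n)
    binsC <- adaptiveBins(g, n)
    for (r in seq_len(n)) {
      for (cc in seq_len(n)) {
        cells[[length(cells) + 1L]] <-
          as.integer(outer((binsR[[r]] - 1L) * g, binsC[[cc]], "+"))
      }
    }
  }
  cells
}

#' Assemble the network
#'
#' @param cfg From [modelConfig()].
#' @return A [PNDNet-class] model with seeded Glorot-initialized weights.
#' @export
assembleNetwork <- function(cfg) {
  backbone <- loadBackbone(cfg$backbone, pretrained = FALSE,
                           seed = cfg$seed)
  base <- if (cfg$backbone == "tiny") c(4L, 4L) else {
    b <- backboneBuilders[[cfg$backbone]](includeTop = FALSE)
    layerShapes(b$layers, c(224, 224, 3))[[b$feature]][1:2]
  }
  ops <- nodePipelineOperators(cfg$region, base)
  P <- if (cfg$noSpp) cfg$region@grid^2L else nodeCount(cfg$region)
  C <- backbone@channels
  gcnC <- if (is.null(cfg$gcnFeatures)) C else as.integer(cfg$gcnFeatures)
  gcn <- if (cfg$gcnEnabled) {
    gcnInit(C, layers = cfg$gcnLayers, cOut = gcnC, seed = cfg$seed + 1L)
  } else list()
  headC <- if (cfg$gcnEnabled) gcnC else C
  head <- withr::with_seed(cfg$seed + 2L, list(
    gamma = rep(1, headC), beta = numeric(headC),
    runMean = numeric(headC), runVar = rep(1, headC),
    W = matrix(glorotUniform(headC, cfg$numClasses, headC * cfg$numClasses),
               headC, cfg$numClasses),
    b = numeric(cfg$numClasses)
  ))
  pipeline <- list(RB = ops$RB, S = ops$S,
                   binCells = pyramidBinCells(cfg$region@grid,
                                              cfg$region@levels),
                   poolMode = cfg$region@poolMode, P = P)
  new("PNDNet", config = cfg, backbone = backbone, pipeline = pipeline,
      adjacency = buildAdjacency(P, "complete"), gcn = gcn, head = head,
      seed = cfg$seed)
}

# nodes from one flattened feature map (hw x C); returns cache for backprop
nodesForward <- function(X, pipeline, noSpp) {
  R <- as.matrix(pipeline$RB %*% X)            # omega x C region descriptors
  if (noSpp) return(list(G = R, R = R, argmax = NULL))
  if (pipeline$poolMode == "average") {
    list(G = as.matrix(pipeline$S %*% R), R = R, argmax = NULL)
  } else {
    P <- length(pipeline$binCells)
    G <- matrix(0, P, ncol(R))
    amx <- matrix(0L, P, ncol(R))
    for (p in seq_len(P)) {
      cells <- pipeline$binCells[[p]]
      blk <- R[cells, , drop = FALSE]
      w <- max.col(t(blk), ties.method = "first")
      amx[p, ] <- cells[w]
      G[p, ] <- blk[cbind(w, seq_len(ncol(R)))]
    }
    list(G = G, R = R, argmax = amx)
  }
}

nodesBackward <- function(dG, cache, pipeline, noSpp) {
  dR <- if (noSpp) dG
  else if (pipeline$poolMode == "average") as.matrix(Matrix::crossprod(pipeline$S, dG))
  else {
    dR <- matrix(0, nrow(cache$R), ncol(cache$R))
    for (p in seq_len(nrow(dG))) {
      idx <- cbind(cache$argmax[p, ], seq_len(ncol(dG)))
      dR[idx] <- dR[idx] + dG[p, ]
    }
    dR
  }
  as.matrix(Matrix::crossprod(pipeline$RB, dR))   # hw x C
}

layerNormForward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  xhat <- xc / sqrt(v + eps)
  list(out = sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+"),
       xhat = xhat, inv = 1 / sqrt(v + eps))
}

layerNormBackward <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, gamma, "*")
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dGamma = colSums(dY * xhat), dBeta = colSums(dY))
}

batchNormForward <- function(X, gamma, beta, runMean, runVar, training,
                             eps = 1e-5) {
  if (training && nrow(X) > 1L) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc^2)
  } else {
    mu <- runMean; v <- runVar
    xc <- sweep(X, 2, mu)
  }
  xhat <- sweep(xc, 2, sqrt(v + eps), "/")
  list(out = sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+"),
       xhat = xhat, inv = 1 / sqrt(v + eps), mu = mu, v = v)
}

batchNormBackward <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- cache$xhat * matrix(colMeans(dxhat * cache$xhat), n,
                            ncol(dY), byrow = TRUE)
  dX <- sweep(t1 - t2, 2, cache$inv, "*")
  list(dX = dX, dGamma = colSums(dY * cache$xhat), dBeta = colSums(dY))
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Categorical cross-entropy loss
#'
#' Mean over the batch of `-sum_i Y_i log(Yhat_i)` with predicted
#' probabilities floored at 1e-12.
#'
#' @param truth One-hot `N x Y` matrix, or a vector of 0-based class labels.
#' @param probs `N x Y` matrix of predicted class probabilities.
#' @return Nonnegative scalar.
#' @export
crossEntropyLoss <- function(truth, probs) {
  if (!is.matrix(truth)) truth <- oneHot(truth, ncol(probs))
  if (!all(dim(truth) == dim(probs))) stop("shape mismatch")
  -mean(rowSums(truth * log(pmax(probs, 1e-12))))
}

oneHot <- function(labels, numClasses) {
  if (any(labels < 0L | labels >= numClasses)) stop("label out of range")
  Y <- matrix(0, length(labels), numClasses)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

# Full forward pass on a preprocessed image batch.  Returns probabilities and
# (when keepCache) everything needed for backprop.
networkForward <- function(model, images, training = FALSE,
                           dropoutSeed = NULL, keepCache = FALSE) {
  cfg <- model@config
  if (length(dim(images)) == 3L) images <- array(images, c(1L, dim(images)))
  n <- dim(images)[1]
  C <- model@backbone@channels
  perImage <- vector("list", n)
  Fmat <- matrix(0, n, if (cfg$gcnEnabled) ncol(model@gcn[[length(model@gcn)]]$W) else C)
  gapIn <- vector("list", n)
  for (i in seq_len(n)) {
    img <- array(images[i, , , ], dim(images)[2:4])
    bb <- if (model@backbone@name == "tiny") {
      tinyBackboneForward(img, model@backbone@params)
    } else {
      list(out = graphForward(model@backbone@layers, model@backbone@params,
                              img, stopAt = model@backbone@featureLayer),
           cache = NULL)
    }
    d <- dim(bb$out)
    X <- matrix(bb$out, d[1] * d[2], d[3])
    nd <- nodesForward(X, model@pipeline, cfg$noSpp)
    gc <- if (cfg$gcnEnabled) {
      gcnForwardInternal(nd$G, model@gcn, model@adjacency@ahat)
    } else list(out = nd$G, cache = NULL)
    Fmat[i, ] <- colMeans(gc$out)
    if (keepCache) perImage[[i]] <- list(bb = bb, nodes = nd, gcn = gc,
                                         mapDim = d)
  }
  norm <- if (cfg$headNorm == "layer") {
    layerNormForward(Fmat, model@head$gamma, model@head$beta)
  } else {
    batchNormForward(Fmat, model@head$gamma, model@head$beta,
                     model@head$runMean, model@head$runVar, training)
  }
  H <- norm$out
  mask <- NULL
  if (training && cfg$dropoutRate > 0) {
    mask <- withr::with_seed(dropoutSeed, {
      matrix(stats::rbinom(length(H), 1, 1 - cfg$dropoutRate), nrow(H)) /
        (1 - cfg$dropoutRate)
    })
    H <- H * mask
  }
  logits <- sweep(H %*% model@head$W, 2, model@head$b, "+")
  probs <- softmaxRows(logits)
  res <- list(probs = probs, logits = logits)
  if (keepCache) {
    res$cache <- list(perImage = perImage, Fmat = Fmat, norm = norm,
                      mask = mask, H = H, n = n)
  }
  res
}

# Backward pass from d(loss)/d(logits); returns gradients for every trained
# parameter group (and, on request, d/d last-conv activations for Grad-CAM).
networkBackward <- function(model, fwd, dLogits, wantActGrad = FALSE) {
  cfg <- model@config
  cache <- fwd$cache
  n <- cache$n
  grads <- list(
    headW = crossprod(cache$H, dLogits),
    headB = colSums(dLogits)
  )
  dH <- dLogits %*% t(model@head$W)
  if (!is.null(cache$mask)) dH <- dH * cache$mask
  nb <- if (cfg$headNorm == "layer") {
    layerNormBackward(dH, cache$norm, model@head$gamma)
  } else {
    batchNormBackward(dH, cache$norm, model@head$gamma)
  }
  grads$gamma <- nb$dGamma
  grads$beta <- nb$dBeta
  dF <- nb$dX
  P <- model@pipeline$P
  if (cfg$gcnEnabled) {
    gcnG <- lapply(model@gcn, function(l)
      list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b))))
  }
  bbG <- NULL
  actGrads <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- cache$perImage[[i]]
    dGout <- matrix(dF[i, ] / P, P, length(dF[i, ]), byrow = TRUE)
    if (cfg$gcnEnabled) {
      gb <- gcnBackwardInternal(dGout, model@gcn, model@adjacency@ahat,
                                pi$gcn$cache)
      for (l in seq_along(gcnG)) {
        gcnG[[l]]$W <- gcnG[[l]]$W + gb$grads[[l]]$W
        gcnG[[l]]$b <- gcnG[[l]]$b + gb$grads[[l]]$b
      }
      dG0 <- gb$dInput
    } else dG0 <- dGout
    dX <- nodesBackward(dG0, pi$nodes, model@pipeline, cfg$noSpp)
    dMap <- array(dX, pi$mapDim)
    if (model@backbone@name == "tiny") {
      tb <- tinyBackboneBackward(dMap, model@backbone@params, pi$bb$cache)
      if (is.null(bbG)) bbG <- tb$weights
      else for (l in seq_along(bbG)) {
        bbG[[l]]$W <- bbG[[l]]$W + tb$weights[[l]]$W
        bbG[[l]]$b <- bbG[[l]]$b + tb$weights[[l]]$b
      }
      if (wantActGrad) actGrads[[i]] <- tb$lastConvAct
    }
  }
  grads$gcn <- if (cfg$gcnEnabled) gcnG else list()
  grads$backbone <- bbG
  if (wantActGrad) grads$actGrads <- actGrads
  grads
}

#' Predict class probabilities
#'
#' Runs the network in evaluation mode (no dropout; normalization in
#' inference form).
#'
#' @param model A [PNDNet-class].
#' @param images Preprocessed image batch.
#' @return `N x Y` matrix of class probabilities (rows sum to 1).
#' @export
predictNetwork <- function(model, images) {
  networkForward(model, images, training = FALSE)$probs
}

#' Training configuration
#'
#' Defaults follow the training protocol: SGD on categorical cross-entropy,
#' learning rate 1e-3 divided by 5 after 100 of 150 epochs, mini-batches of
#' 12, no early stopping.  `preset = "alternate"` switches to the alternate
#' recipe (learning rate 0.007, batch size 8).
#'
#' @param learningRate Initial learning rate.
#' @param epochs Training epochs.
#' @param batchSize Mini-batch size.
#' @param lrDropFactor Learning-rate divisor applied after `lrDropEpoch`.
#' @param lrDropEpoch Epoch after which the learning rate is divided.
#' @param momentum SGD momentum (default 0.9).
#' @param augment `NULL` for no augmentation or an [augmentConfig()] list.
#' @param freezeBackbone Train only the graph module and head, leaving
#'   backbone weights fixed.
#' @param preset `"default"` or `"alternate"`.
#' @param seed Seed governing shuffling, dropout and augmentation.
#' @return Validated configuration list.
#' @export
trainConfig <- function(learningRate = 1e-3, epochs = 150L, batchSize = 12L,
                        lrDropFactor = 5, lrDropEpoch = 100L, momentum = 0.9,
                        augment = NULL, freezeBackbone = FALSE,
                        preset = c("default", "alternate"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "alternate") { learningRate <- 0.007; batchSize <- 8L }
  if (learningRate <= 0) stop("learningRate must be positive")
  if (lrDropEpoch > epochs && epochs > 0L)
    stop("lrDropEpoch must not exceed epochs")
  list(learningRate = learningRate, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), lrDropFactor = lrDropFactor,
       lrDropEpoch = as.integer(lrDropEpoch), momentum = momentum,
       augment = augment, freezeBackbone = isTRUE(freezeBackbone),
       preset = preset, seed = as.integer(seed))
}

applyUpdate <- function(p, g, v, lr, mom) {
  v <- mom * v - lr * g
  list(p = p + v, v = v)
}

#' Train the network with SGD
#'
#' @param model A [PNDNet-class] from [assembleNetwork()].
#' @param images `N x H x W x 3` raw RGB training images on the \[0, 255\]
#'   scale (preprocessing is applied internally).
#' @param labels 0-based class labels.
#' @param tc From [trainConfig()].
#' @param valImages,valLabels Optional validation set; when given, the model
#'   with the best validation top-1 is returned (no early stopping).
#' @param verbose Print per-epoch progress.
#' @return List with `model` (trained), `best` (best-validation model, equal
#'   to `model` when no validation set is given) and `history` (data.frame
#'   epoch, lr, loss, top1, valTop1).
#' @export
trainNetwork <- function(model, images, labels, tc = trainConfig(),
                         valImages = NULL, valLabels = NULL, verbose = FALSE) {
  if (length(labels) == 0L) stop("training set is empty")
  if (model@backbone@name != "tiny" && !tc$freezeBackbone)
    stop("end-to-end training is supported for the tiny backbone; use ",
         "freezeBackbone = TRUE to train the graph module and head on a ",
         "fixed backbone")
  cfg <- model@config
  Y <- oneHot(labels, cfg$numClasses)
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        loss = numeric(0), top1 = numeric(0),
                        valTop1 = numeric(0))
  if (tc$epochs == 0L)
    return(list(model = model, best = model, history = history))

  vel <- list()   # momentum buffers, lazily keyed
  getVel <- function(key, g) if (is.null(vel[[key]])) 0 * g else vel[[key]]
  bestVal <- -Inf
  bestModel <- model
  prep <- function(imgs) preprocessImages(imgs)
  valPrep <- if (!is.null(valImages)) prep(valImages) else NULL

  for (epoch in seq_len(tc$epochs)) {
    lr <- if (epoch > tc$lrDropEpoch) tc$learningRate / tc$lrDropFactor
          else tc$learningRate
    epImages <- images
    if (!is.null(tc$augment)) {
      cs <- tc$augment$cropSize
      epImages <- array(0, c(dim(images)[1], cs, cs, 3L))
      for (i in seq_len(dim(images)[1])) {
        epImages[i, , , ] <- augmentImage(
          array(images[i, , , ], dim(images)[2:4]), tc$augment,
          seed = tc$seed + epoch * 100003L + i)
      }
    }
    epImages <- prep(epImages)
    order <- withr::with_seed(tc$seed + epoch, sample(length(labels)))
    batches <- split(order, ceiling(seq_along(order) / tc$batchSize))
    epochLoss <- 0; nCorrect <- 0
    for (bi in seq_along(batches)) {
      ids <- batches[[bi]]
      xb <- epImages[ids, , , , drop = FALSE]
      yb <- Y[ids, , drop = FALSE]
      fwd <- networkForward(model, xb, training = TRUE,
                            dropoutSeed = tc$seed + epoch * 1009L + bi,
                            keepCache = TRUE)
      loss <- crossEntropyLoss(yb, fwd$probs)
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      epochLoss <- epochLoss + loss * length(ids)
      nCorrect <- nCorrect +
        sum(max.col(fwd$probs, "first") == max.col(yb, "first"))
      dLogits <- (fwd$probs - yb) / length(ids)
      g <- networkBackward(model, fwd, dLogits)

      head <- model@head
      for (nm in c("W", "b", "gamma", "beta")) {
        gk <- switch(nm, W = g$headW, b = g$headB, gamma = g$gamma,
                     beta = g$beta)
        up <- applyUpdate(head[[nm]], gk, getVel(paste0("head.", nm), gk),
                          lr, tc$momentum)
        head[[nm]] <- up$p
        vel[[paste0("head.", nm)]] <- up$v
      }
      if (cfg$headNorm == "batch") {
        head$runMean <- 0.9 * head$runMean + 0.1 * fwd$cache$norm$mu
        head$runVar <- 0.9 * head$runVar + 0.1 * fwd$cache$norm$v
      }
      gcn <- model@gcn
      if (cfg$gcnEnabled) {
        for (l in seq_along(gcn)) {
          for (nm in c("W", "b")) {
            key <- sprintf("gcn%d.%s", l, nm)
            up <- applyUpdate(gcn[[l]][[nm]], g$gcn[[l]][[nm]],
                              getVel(key, g$gcn[[l]][[nm]]), lr, tc$momentum)
            gcn[[l]][[nm]] <- up$p
            vel[[key]] <- up$v
          }
        }
      }
      bb <- model@backbone
      if (!tc$freezeBackbone && bb@name == "tiny") {
        params <- bb@params
        for (l in seq_along(params)) {
          for (nm in c("W", "b")) {
            key <- sprintf("bb%d.%s", l, nm)
            up <- applyUpdate(params[[l]][[nm]], g$backbone[[l]][[nm]],
                              getVel(key, g$backbone[[l]][[nm]]), lr,
                              tc$momentum)
            params[[l]][[nm]] <- up$p
            vel[[key]] <- up$v
          }
        }
        bb <- methods::initialize(bb, params = params)
      }
      model <- methods::initialize(model, head = head, gcn = gcn,
                                   backbone = bb)
    }
    trainTop1 <- nCorrect / length(labels)
    valTop1 <- NA_real_
    if (!is.null(valPrep)) {
      vp <- predictNetwork(model, valPrep)
      valTop1 <- mean(max.col(vp, "first") - 1L == valLabels)
      if (valTop1 >= bestVal) { bestVal <- valTop1; bestModel <- model }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, loss = epochLoss / length(labels),
      top1 = trainTop1, valTop1 = valTop1))
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  top1 %.3f  val %.3f",
                      epoch, lr, epochLoss / length(labels), trainTop1,
                      valTop1))
  }
  if (is.null(valPrep)) bestModel <- model
  list(model = model, best = bestModel, history = history)
}
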