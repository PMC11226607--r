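# Evaluation: confusion matrices, one-vs-rest precision/recall/F1, top-k
# accuracy, the hold-out and five-fold protocols, Grad-CAM heatmaps and 2-D
# embedding export of penultimate features.

#' Confusion matrix from label vectors
#'
#' @param truth,predicted 0-based class labels in `[0, Y)`.
#' @param numClasses Y.
#' @param classNames Optional labels.
#' @return A [ConfusionMatrix-class]; rows are true classes, columns
#'   predicted.
#' @export
confusion <- function(truth, predicted, numClasses,
                      classNames = as.character(seq_len(numClasses) - 1L)) {
  if (length(truth) != length(predicted)) stop("label vectors differ in length")
  if (any(c(truth, predicted) < 0L) || any(c(truth, predicted) >= numClasses))
    stop("label out of range")
  counts <- matrix(0L, numClasses, numClasses)
  for (i in seq_along(truth))
    counts[truth[i] + 1L, predicted[i] + 1L] <-
      counts[truth[i] + 1L, predicted[i] + 1L] + 1L
  new("ConfusionMatrix", counts = counts, classNames = classNames)
}

#' Metrics from a confusion matrix
#'
#' One-vs-rest TP/FP/FN per class give precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and `F1 = 2PR/(P+R)`; zero-denominator cases are defined as
#' 0.  Accuracy is the trace over the total.  Aggregate values are unweighted
#' (macro) means.
#'
#' @param cm A [ConfusionMatrix-class] with at least one sample.
#' @return List with `accuracy`, `perClass` data.frame and `macro` named
#'   vector.
#' @export
metricsFromConfusion <- function(cm) {
  counts <- cm@counts
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- safe(2 * precision * recall, precision + recall)
  list(accuracy = sum(tp) / total,
       perClass = data.frame(class = cm@classNames, precision = precision,
                             recall = recall, f1 = f1, support = rowSums(counts)),
       macro = c(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)))
}

#' Top-k accuracy
#'
#' Fraction of samples whose true class is among the k most probable
#' predictions; ties are broken in favour of the lower class index.
#'
#' @param probs `N x Y` class-probability (or score) matrix.
#' @param truth 0-based true labels.
#' @param k Number of top classes considered (1 <= k <= Y).
#' @return Fraction in \[0, 1\].
#' @export
topkAccuracy <- function(probs, truth, k) {
  if (k < 1L) stop("k must be at least 1")
  if (k > ncol(probs)) stop("k cannot exceed the number of classes")
  hits <- vapply(seq_len(nrow(probs)), function(i) {
    top <- order(-probs[i, ], seq_len(ncol(probs)))[seq_len(k)]
    (truth[i] + 1L) %in% top
  }, logical(1))
  mean(hits)
}

#' Evaluate a trained model on labelled images
#'
#' @param model A [PNDNet-class].
#' @param images Raw RGB images on the \[0, 255\] scale.
#' @param labels 0-based true labels.
#' @param classNames Optional class labels.
#' @return A [MetricsReport-class].
#' @export
evaluateModel <- function(model, images, labels,
                          classNames = as.character(seq_len(model@config$numClasses) - 1L)) {
  probs <- predictNetwork(model, preprocessImages(images))
  Y <- model@config$numClasses
  cm <- confusion(labels, max.col(probs, "first") - 1L, Y, classNames)
  m <- metricsFromConfusion(cm)
  new("MetricsReport",
      top1 = topkAccuracy(probs, labels, 1L),
      top3 = topkAccuracy(probs, labels, min(3L, Y)),
      perClass = m$perClass, macro = m$macro, confusion = cm)
}

reportRow <- function(label, report) {
  data.frame(fold = label,
             valAcc = NA_real_, testAcc = report@top1 * 100,
             top3 = report@top3 * 100,
             precision = report@macro[["precision"]] * 100,
             recall = report@macro[["recall"]] * 100,
             f1 = report@macro[["f1"]] * 100)
}

#' Run the hold-out or k-fold evaluation protocol
#'
#' `mode = "holdout"` trains on the training pool and reports on the test
#' set.  `mode = "kfold"` trains once per fold (training on (k-1)/k of the
#' pool, validating on the remaining fold, testing on the shared test set)
#' and reports one row per fold plus their arithmetic mean ("Avg") — the
#' layout of the cross-validation tables.  Percentages are reported to two
#' decimals.
#'
#' @param cfg Model configuration from [modelConfig()].
#' @param tc Training configuration from [trainConfig()].
#' @param index A [DatasetIndex-class].
#' @param plan A [SplitPlan-class]; for `"kfold"` it must carry folds.
#' @param mode `"holdout"` or `"kfold"`.
#' @param outDir Optional directory for report files (metrics JSON, table and
#'   confusion CSVs).
#' @param verbose Print training progress.
#' @return List with `table` (data.frame of result rows), `reports`
#'   (per-run [MetricsReport-class] objects) and `models`.
#' @export
runProtocol <- function(cfg, tc, index, plan, mode = c("holdout", "kfold"),
                        outDir = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "kfold" && !length(plan@folds))
    stop("kfold protocol requires a plan with folds (see makeFolds)")
  test <- loadImages(index, plan@testIds)
  reports <- list(); models <- list()
  rows <- NULL
  runs <- if (mode == "holdout") {
    list(list(label = "holdout", train = plan@trainIds, val = integer(0)))
  } else {
    lapply(seq_along(plan@folds), function(f)
      list(label = sprintf("Fold-%d", f), train = plan@folds[[f]]$train,
           val = plan@folds[[f]]$val))
  }
  for (r in runs) {
    tr <- loadImages(index, r$train)
    va <- if (length(r$val)) loadImages(index, r$val) else NULL
    model <- assembleNetwork(cfg)
    fit <- trainNetwork(model, tr$images, tr$labels, tc,
                        valImages = if (is.null(va)) NULL else va$images,
                        valLabels = if (is.null(va)) NULL else va$labels,
                        verbose = verbose)
    rep <- evaluateModel(fit$best, test$images, test$labels,
                         classNames = index@classNames)
    row <- reportRow(r$label, rep)
    if (!is.null(va)) {
      vp <- predictNetwork(fit$best, preprocessImages(va$images))
      row$valAcc <- topkAccuracy(vp, va$labels, 1L) * 100
    }
    rows <- rbind(rows, row)
    reports[[r$label]] <- rep
    models[[r$label]] <- fit$best
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(fit$history,
                       file.path(outDir, sprintf("history_%s.csv", r$label)),
                       row.names = FALSE)
    }
  }
  if (mode == "kfold") {
    avg <- rows[1, ]
    avg$fold <- "Avg"
    for (nm in setdiff(names(rows), "fold")) avg[[nm]] <- mean(rows[[nm]])
    rows <- rbind(rows, avg)
  }
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], round, 2)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rows, file.path(outDir, "results.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(reports, function(rp) list(
        top1 = rp@top1, top3 = rp@top3, macro = as.list(rp@macro))),
      file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    for (nm in names(reports)) {
      utils::write.csv(confusionCounts(reports[[nm]]@confusion),
                       file.path(outDir, sprintf("confusion_%s.csv", nm)),
                       row.names = FALSE)
    }
  }
  list(table = rows, reports = reports, models = models)
}

#' Grad-CAM heatmap
#'
#' Gradient-weighted class-activation map: channel weights are the spatial
#' means of the target-class score gradient at the last backbone
#' convolutional stage; the weighted, ReLU-rectified activation sum is
#' min-max normalized and bilinearly resized to the input size.  A constant
#' map (e.g. under uniform activations and gradients) is defined as all
#' zeros.
#'
#' @param model A [PNDNet-class] with the tiny backbone (the differentiable
#'   path).
#' @param image Raw RGB `H x W x 3` image on the \[0, 255\] scale.
#' @param targetClass 0-based class whose evidence is mapped.
#' @return `H x W` matrix with values in \[0, 1\].
#' @export
gradCAM <- function(model, image, targetClass) {
  if (model@backbone@name != "tiny")
    stop("Grad-CAM requires the differentiable (tiny) backbone path")
  Y <- model@config$numClasses
  if (targetClass < 0L || targetClass >= Y) stop("target class out of range")
  x <- preprocessImages(image)
  fwd <- networkForward(model, x, training = FALSE, keepCache = TRUE)
  dLogits <- matrix(0, 1, Y)
  dLogits[1, targetClass + 1L] <- 1
  g <- networkBackward(model, fwd, dLogits, wantActGrad = TRUE)
  act <- fwd$cache$perImage[[1]]$bb$cache$a3
  grad <- g$actGrads[[1]]
  alpha <- apply(grad, 3, mean)
  cam <- pmax(apply(sweep(act, 3, alpha, "*"), c(1, 2), sum), 0)
  if (diff(range(cam)) < 1e-12) return(matrix(0, dim(image)[1], dim(image)[2]))
  up <- upsampleMap(array(cam, c(dim(cam), 1L)), dim(image)[1:2])[, , 1]
  rng <- range(up)
  if (diff(rng) < 1e-12) return(matrix(0, dim(image)[1], dim(image)[2]))
  (up - rng[1]) / diff(rng)
}

#' Penultimate feature vectors
#'
#' The normalized pooled C-vector (input of the softmax layer, dropout off).
#'
#' @param model A [PNDNet-class].
#' @param images Raw RGB images on the \[0, 255\] scale.
#' @return `N x C` matrix.
#' @export
penultimateFeatures <- function(model, images) {
  x <- preprocessImages(images)
  fwd <- networkForward(model, x, training = FALSE, keepCache = TRUE)
  fwd$cache$norm$out
}

# Exact (O(n^2)) t-SNE with perplexity calibration by bisection, early
# exaggeration and momentum gradient descent.  Problem sizes here are a few
# hundred points, where the exact method is both fast and the reference
# formulation.
tsneEmbed <- function(X, perplexity = NULL, iters = 400L, seed = 1L) {
  n <- nrow(X)
  if (is.null(perplexity)) perplexity <- max(2, min(30, floor((n - 1) / 3)))
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  target <- log(perplexity)
  for (i in seq_len(n)) {
    lo <- 1e-20; hi <- 1e20; beta <- 1
    di <- D2[i, -i]
    for (it in 1:60) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s < 1e-300) { hi <- beta; beta <- (lo + hi) / 2; next }
      p <- p / s
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (hi == 1e20) beta * 2 else (lo + hi) / 2 }
      else { hi <- beta; beta <- (lo + hi) / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withr::with_seed(seed, {
    Ycur <- matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2)
  })
  vel <- matrix(0, n, 2)
  for (it in seq_len(iters)) {
    ex <- if (it <= 100L) 4 else 1
    mom <- if (it <= 250L) 0.5 else 0.8
    d2 <- as.matrix(stats::dist(Ycur))^2
    W <- 1 / (1 + d2); diag(W) <- 0
    Q <- pmax(W / sum(W), 1e-12)
    M <- (ex * P - Q) * W
    grad <- 4 * (diag(rowSums(M)) %*% Ycur - M %*% Ycur)
    vel <- mom * vel - 200 * grad
    Ycur <- Ycur + vel
    Ycur <- sweep(Ycur, 2, colMeans(Ycur))
  }
  Ycur
}

#' Export a 2-D embedding of penultimate features
#'
#' Embeds the penultimate feature vectors of a dataset in two dimensions
#' (exact t-SNE, seed-controlled) and writes (x, y, label) rows.
#'
#' @param model A [PNDNet-class].
#' @param images Raw RGB images (at least 10).
#' @param labels 0-based class labels.
#' @param path Optional CSV output path.
#' @param perplexity t-SNE perplexity (default adapts to n).
#' @param seed Integer seed; fixed seed gives an identical embedding.
#' @return data.frame with columns `x`, `y`, `label` (invisibly if written).
#' @export
tsneExport <- function(model, images, labels, path = NULL, perplexity = NULL,
                       seed = 1L) {
  n <- if (length(dim(images)) == 4L) dim(images)[1] else 1L
  if (n < 10L) stop("at least 10 samples are required for an embedding")
  feats <- penultimateFeatures(model, images)
  emb <- tsneEmbed(feats, perplexity = perplexity, seed = seed)
  out <- data.frame(x = emb[, 1], y = emb[, 2], label = labels)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
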