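test_that("confusion counts accumulate per (truth, prediction) pair", {
  cm <- confusion(c(0L, 1L, 1L), c(0L, 1L, 0L), 2L)
  expect_equal(confusionCounts(cm),
               matrix(c(1L, 1L, 0L, 1L), 2, 2), ignore_attr = TRUE)
  perfect <- confusion(0:3, 0:3, 4L)
  expect_equal(confusionCounts(perfect), diag(4), ignore_attr = TRUE)
  set.seed(61)
  t <- sample(0:4, 200, TRUE); p <- sample(0:4, 200, TRUE)
  cm2 <- confusion(t, p, 5L)
  expect_equal(rowSums(confusionCounts(cm2)),
               as.numeric(table(factor(t, levels = 0:4))),
               ignore_attr = TRUE)
  expect_equal(sum(confusionCounts(cm2)), 200)
  expect_error(confusion(c(0L, 5L), c(0L, 1L), 2L), "out of range")
})

test_that("precision/recall/F1 match hand arithmetic", {
  # binary case: TP = 5, FP = 5, FN = 0
  cm <- methods::new("ConfusionMatrix",
                     counts = matrix(c(5L, 5L, 0L, 0L), 2, 2),
                     classNames = c("pos", "neg"))
  m <- metricsFromConfusion(cm)
  expect_equal(m$perClass$precision[1], 0.5)
  expect_equal(m$perClass$recall[1], 1.0)
  expect_equal(m$perClass$f1[1], 2 * 0.5 * 1 / 1.5, tolerance = 1e-12)
  # accuracy: TP = 90, TN = 5, FP = 3, FN = 2
  cm2 <- methods::new("ConfusionMatrix",
                      counts = matrix(c(90L, 3L, 2L, 5L), 2, 2),
                      classNames = c("a", "b"))
  expect_equal(metricsFromConfusion(cm2)$accuracy, 0.95)
  # perfect classifier
  m3 <- metricsFromConfusion(confusion(0:2, 0:2, 3L))
  expect_equal(m3$accuracy, 1)
  expect_equal(unname(m3$macro), c(1, 1, 1))
})

test_that("metrics agree with per-sample one-vs-rest tallies", {
  set.seed(67)
  for (rep in 1:50) {
    Y <- sample(2:6, 1)
    n <- sample(10:60, 1)
    t <- sample(0:(Y - 1), n, TRUE)
    p <- sample(0:(Y - 1), n, TRUE)
    m <- metricsFromConfusion(confusion(t, p, Y))
    for (cls in 0:(Y - 1)) {
      tp <- sum(t == cls & p == cls)
      fp <- sum(t != cls & p == cls)
      fn <- sum(t == cls & p != cls)
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      expect_equal(m$perClass$precision[cls + 1], prec, tolerance = 1e-12)
      expect_equal(m$perClass$recall[cls + 1], rec, tolerance = 1e-12)
      expect_equal(m$perClass$f1[cls + 1], f1, tolerance = 1e-12)
    }
    expect_equal(m$accuracy, mean(t == p), tolerance = 1e-12)
    expect_gte(m$macro[["f1"]], min(m$perClass$f1) - 1e-12)
    expect_lte(m$macro[["f1"]], max(m$perClass$f1) + 1e-12)
  }
})

test_that("top-k accuracy obeys its boundary cases and tie rule", {
  set.seed(71)
  probs <- matrix(runif(40), 10, 4)
  probs <- probs / rowSums(probs)
  truth <- sample(0:3, 10, TRUE)
  expect_equal(topkAccuracy(probs, truth, 4L), 1.0)
  argmaxAcc <- mean(max.col(probs, "first") - 1L == truth)
  expect_equal(topkAccuracy(probs, truth, 1L), argmaxAcc)
  # ties break toward the lower class index
  tied <- matrix(0.25, 2, 4)
  expect_equal(topkAccuracy(tied, c(0L, 3L), 2L), 0.5)
  expect_error(topkAccuracy(probs, truth, 0L), "at least 1")
  expect_error(topkAccuracy(probs, truth, 5L), "exceed")
})

test_that("top-3 of random 10-class scores approaches 3/10", {
  set.seed(73)
  n <- 20000L
  probs <- matrix(runif(n * 10), n, 10)
  truth <- sample(0:9, n, TRUE)
  acc <- topkAccuracy(probs, truth, 3L)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(acc - 0.3), 3 * se)
})

test_that("five-fold protocol reports one row per fold plus their mean", {
  idx <- indexDataset(synthFixture(3L, 10L, 64L, seed = 31L))
  plan <- makeFolds(makeSplit(idx, 0.3, seed = 2L), 5L)
  cfg <- modelConfig(numClasses = 3L, seed = 1L)
  tc <- trainConfig(learningRate = 0.02, epochs = 2L, batchSize = 7L,
                    lrDropEpoch = 2L, seed = 1L)
  out <- file.path(tempdir(), "cv-report")
  res <- runProtocol(cfg, tc, idx, plan, "kfold", outDir = out)
  expect_equal(nrow(res$table), 6L)
  expect_equal(res$table$fold, c(paste0("Fold-", 1:5), "Avg"))
  for (col in c("valAcc", "testAcc", "top3", "f1")) {
    expect_equal(res$table[[col]][6], round(mean(res$table[[col]][1:5]), 2),
                 tolerance = 0.01)
  }
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_true(file.exists(file.path(out, "history_Fold-1.csv")))
  # top3 >= top1 on every generated report
  for (rp in res$reports) expect_gte(rp@top3, rp@top1)
})

test_that("hold-out protocol on the separable fixture beats chance", {
  fix <- trainedTinyFixture()
  idx <- fix$index
  plan <- makeSplit(idx, 0.3, seed = 5L)
  test <- loadImages(idx, plan@testIds)
  rep <- evaluateModel(fix$model, test$images, test$labels)
  expect_gt(rep@top1, 1 / 3)
  expect_gte(rep@top3, rep@top1)
  expect_equal(sum(confusionCounts(rep@confusion)), length(plan@testIds))
})

test_that("Grad-CAM heatmaps are normalized to the input size", {
  fix <- trainedTinyFixture()
  img <- array(loadImages(fix$index, 1L)$images[1, , , ], c(64, 64, 3))
  cam <- gradCAM(fix$model, img, 0L)
  expect_equal(dim(cam), c(64L, 64L))
  expect_gte(min(cam), 0)
  expect_lte(max(cam), 1)
  expect_equal(max(cam), 1, tolerance = 1e-9)   # min-max normalized
  expect_error(gradCAM(fix$model, img, 7L), "out of range")
})

test_that("a spatially constant activation map yields the all-zero heatmap", {
  model <- assembleNetwork(modelConfig(numClasses = 3L, seed = 8L))
  p <- model@backbone@params
  p[[3]]$W[] <- 0            # third conv block: constant activation map
  p[[3]]$b[] <- 1
  model@backbone <- methods::initialize(model@backbone, params = p)
  img <- array(randomImageBatch(1, 64)[1, , , ], c(64, 64, 3))
  cam <- gradCAM(model, img, 1L)
  expect_equal(max(abs(cam)), 0)
})

test_that("2-D embedding export is deterministic and keeps duplicates close", {
  fix <- trainedTinyFixture()
  dat <- loadImages(fix$index, 1:12)
  imgs <- dat$images
  imgs[12, , , ] <- imgs[1, , , ]    # exact duplicate pair
  emb1 <- tsneExport(fix$model, imgs, dat$labels)
  emb2 <- tsneExport(fix$model, imgs, dat$labels)
  expect_equal(nrow(emb1), 12L)
  expect_identical(emb1, emb2)
  xy <- as.matrix(emb1[, c("x", "y")])
  dupDist <- sqrt(sum((xy[1, ] - xy[12, ])^2))
  allDist <- as.numeric(stats::dist(xy))
  expect_lt(dupDist, stats::median(allDist) / 4)
  path <- file.path(tempdir(), "emb.csv")
  tsneExport(fix$model, imgs, dat$labels, path = path)
  expect_true(file.exists(path))
  expect_error(tsneExport(fix$model, imgs[1:4, , , ], dat$labels[1:4]),
               "at least 10")
})
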