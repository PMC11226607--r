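test_that("assembled network outputs well-formed class probabilities", {
  model <- assembleNetwork(modelConfig(numClasses = 3L, seed = 4L))
  x <- preprocessImages(randomImageBatch(2, 64))
  probs <- predictNetwork(model, x)
  expect_equal(dim(probs), c(2L, 3L))
  expect_equal(rowSums(probs), c(1, 1), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  expect_identical(probs, predictNetwork(model, x))   # eval-mode determinism
})

test_that("cross-entropy matches its closed forms", {
  perfect <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  expect_equal(crossEntropyLoss(c(0L, 1L), perfect), 0)
  uniform <- matrix(1 / 8, 4, 8)
  expect_equal(crossEntropyLoss(rep(2L, 4), uniform), log(8),
               tolerance = 1e-12)
  half <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(crossEntropyLoss(0L, half), log(2), tolerance = 1e-12)
  expect_error(crossEntropyLoss(matrix(1, 2, 2), matrix(0.5, 2, 3)),
               "mismatch")
})

test_that("pooled features equal brute-force column means of the node output", {
  model <- assembleNetwork(modelConfig(numClasses = 3L, seed = 6L))
  x <- preprocessImages(randomImageBatch(1, 64))
  fwd <- pndnet:::networkForward(model, x, keepCache = TRUE)
  G <- fwd$cache$perImage[[1]]$gcn$out
  byHand <- vapply(seq_len(ncol(G)), function(j) {
    s <- 0
    for (i in seq_len(nrow(G))) s <- s + G[i, j]
    s / nrow(G)
  }, numeric(1))
  expect_equal(fwd$cache$Fmat[1, ], byHand, tolerance = 1e-12)
})

test_that("ablation switches change the graph stage exactly as configured", {
  x <- preprocessImages(randomImageBatch(2, 64))
  noGcn <- assembleNetwork(modelConfig(numClasses = 3L, gcnEnabled = FALSE,
                                       seed = 2L))
  expect_length(noGcn@gcn, 0L)
  p1 <- predictNetwork(noGcn, x)
  expect_equal(rowSums(p1), c(1, 1), tolerance = 1e-6)
  noSpp <- assembleNetwork(modelConfig(numClasses = 3L, noSpp = TRUE,
                                       seed = 2L))
  expect_equal(nrow(noSpp@adjacency@ahat), 16L)   # nodes = g^2 regions
  expect_equal(rowSums(predictNetwork(noSpp, x)), c(1, 1), tolerance = 1e-6)
  ro <- assembleNetwork(modelConfig(numClasses = 3L, regionsOnly = TRUE,
                                    seed = 2L))
  expect_length(ro@gcn, 0L)
  expect_equal(nrow(ro@adjacency@ahat), 16L)
  expect_equal(rowSums(predictNetwork(ro, x)), c(1, 1), tolerance = 1e-6)
  oneLayer <- assembleNetwork(modelConfig(numClasses = 3L, gcnLayers = 1L,
                                          seed = 2L))
  expect_length(oneLayer@gcn, 1L)
})

test_that("post-GAP features are invariant to node permutation", {
  set.seed(51)
  G0 <- matrix(rnorm(13 * 8), 13, 8)
  params <- gcnInit(8L, layers = 2L, seed = 1L)
  adj <- buildAdjacency(13L)
  perm <- sample(13)
  out1 <- colMeans(nodeValues(gcnForward(G0, params, adj)))
  out2 <- colMeans(nodeValues(gcnForward(G0[perm, ], params, adj)))
  expect_equal(out1, out2, tolerance = 1e-10)
})

test_that("learning rate is divided by the drop factor after the drop epoch", {
  fix <- trainedTinyFixture()
  h <- fix$history
  expect_equal(unique(h$lr[h$epoch <= 6]), 0.02)
  expect_equal(unique(h$lr[h$epoch > 6]), 0.02 / 5)
})

test_that("training reduces the loss on the synthetic task", {
  h <- trainedTinyFixture()$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_gt(h$top1[nrow(h)], h$top1[1])
})

test_that("zero epochs return the initialized model and empty history", {
  model <- assembleNetwork(modelConfig(numClasses = 3L, seed = 9L))
  dat <- randomImageBatch(4, 64)
  fit <- trainNetwork(model, dat, rep(0:1, 2),
                      trainConfig(epochs = 0L, lrDropEpoch = 0L))
  expect_identical(fit$model@head, model@head)
  expect_equal(nrow(fit$history), 0L)
})

test_that("dropout is inactive in evaluation mode and seeded in training", {
  model <- assembleNetwork(modelConfig(numClasses = 3L, seed = 12L))
  x <- preprocessImages(randomImageBatch(3, 64))
  f1 <- pndnet:::networkForward(model, x, training = TRUE, dropoutSeed = 5L)
  f2 <- pndnet:::networkForward(model, x, training = TRUE, dropoutSeed = 5L)
  f3 <- pndnet:::networkForward(model, x, training = TRUE, dropoutSeed = 6L)
  expect_identical(f1$probs, f2$probs)
  expect_false(identical(f1$probs, f3$probs))
  expect_identical(predictNetwork(model, x), predictNetwork(model, x))
})

test_that("training configuration validates its invariants", {
  expect_error(trainConfig(learningRate = 0), "positive")
  expect_error(trainConfig(epochs = 10L, lrDropEpoch = 20L), "lrDropEpoch")
  alt <- trainConfig(preset = "alternate", epochs = 10L, lrDropEpoch = 5L)
  expect_equal(alt$learningRate, 0.007)
  expect_equal(alt$batchSize, 8L)
  expect_error(modelConfig(numClasses = 1L), "numClasses")
  expect_error(modelConfig(numClasses = 3L, dropoutRate = 1), "dropoutRate")
})
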