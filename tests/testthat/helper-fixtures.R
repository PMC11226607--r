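# Shared fixtures, generated once per test session.

.fixtures <- new.env(parent = emptyenv())

# synthetic class-per-folder dataset, cached by its parameters
synthFixture <- function(nClasses = 3L, perClass = 20L, size = 64L,
                         seed = 11L) {
  key <- sprintf("synth_%d_%d_%d_%d", nClasses, perClass, size, seed)
  if (is.null(.fixtures[[key]])) {
    dir <- file.path(tempdir(), key)
    generateDataset(syntheticSpec(nClasses, perClass, size, seed = seed), dir)
    .fixtures[[key]] <- dir
  }
  .fixtures[[key]]
}

# small trained model on the 3-class fixture, cached (several tests need one)
trainedTinyFixture <- function() {
  if (is.null(.fixtures$trained)) {
    idx <- indexDataset(synthFixture())
    dat <- loadImages(idx)
    model <- assembleNetwork(modelConfig(numClasses = 3L, seed = 1L))
    tc <- trainConfig(learningRate = 0.02, epochs = 8L, batchSize = 12L,
                      lrDropEpoch = 6L, seed = 1L)
    fit <- trainNetwork(model, dat$images, dat$labels, tc)
    .fixtures$trained <- list(model = fit$model, index = idx, data = dat,
                              history = fit$history)
  }
  .fixtures$trained
}

randomImageBatch <- function(n, size = 64L, seed = 99L) {
  withr::with_seed(seed, array(stats::runif(n * size * size * 3, 0, 255),
                               c(n, size, size, 3)))
}
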