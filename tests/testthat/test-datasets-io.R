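test_that("indexing enumerates every image with dense lexicographic classes", {
  dir <- synthFixture(8L, 5L, 64L, seed = 3L)
  idx <- indexDataset(dir)
  expect_equal(nrow(idx@records), 40L)
  expect_equal(idx@classNames, sort(idx@classNames, method = "radix"))
  expect_equal(sort(unique(idx@records$classId)), 0:7)
  idx2 <- indexDataset(dir)
  expect_identical(idx@records, idx2@records)
})

test_that("empty class folders and unreadable images are surfaced", {
  root <- file.path(tempdir(), "idx-bad")
  dir.create(file.path(root, "class_a"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(root, "class_b"), showWarnings = FALSE)
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(root, "class_a", "ok.png"))
  expect_error(indexDataset(root), "no readable images")
  writeLines("not a png", file.path(root, "class_b", "broken.png"))
  png::writePNG(array(0.2, c(8, 8, 3)), file.path(root, "class_b", "ok.png"))
  idx <- indexDataset(root)
  expect_length(idx@skipped, 1L)
  expect_match(idx@skipped, "broken")
  expect_equal(nrow(idx@records), 2L)
})

test_that("hold-out split is stratified, exact and deterministic", {
  dir <- synthFixture(2L, 50L, 64L, seed = 8L)
  idx <- indexDataset(dir)
  plan <- makeSplit(idx, 0.30, seed = 4L)
  expect_length(plan@trainIds, 70L)
  expect_length(plan@testIds, 30L)
  lab <- idx@records$classId
  expect_equal(unname(table(lab[plan@testIds])), c(15L, 15L),
               ignore_attr = TRUE)
  expect_equal(unname(table(lab[plan@trainIds])), c(35L, 35L),
               ignore_attr = TRUE)
  plan2 <- makeSplit(idx, 0.30, seed = 4L)
  expect_identical(plan@trainIds, plan2@trainIds)
  expect_identical(plan@testIds, plan2@testIds)
  expect_length(intersect(plan@trainIds, plan@testIds), 0L)
})

test_that("the 8-class fixture splits 280/120 at 70:30", {
  idx <- indexDataset(synthFixture(8L, 50L, 64L, seed = 9L))
  plan <- makeSplit(idx, 0.30, seed = 1L)
  expect_length(plan@trainIds, 280L)
  expect_length(plan@testIds, 120L)
})

test_that("fold validation sets partition the training pool exactly", {
  idx <- indexDataset(synthFixture(2L, 50L, 64L, seed = 8L))
  plan <- makeFolds(makeSplit(idx, 0.30, seed = 4L), 5L)
  expect_length(plan@folds, 5L)
  vals <- lapply(plan@folds, `[[`, "val")
  expect_equal(sort(unlist(vals)), sort(plan@trainIds))
  for (f in plan@folds) {
    expect_length(intersect(f$train, f$val), 0L)
    expect_equal(sort(c(f$train, f$val)), sort(plan@trainIds))
    expect_length(f$val, 14L)
    expect_length(f$train, 56L)
  }
})

test_that("a 2010-image training pool folds into 1608/402 per fold", {
  # class sizes mirroring a realistic 7-class disease set
  sizes <- c(300L, 305L, 280L, 290L, 295L, 270L, 270L)
  labels <- rep(seq_along(sizes) - 1L, sizes)
  n <- length(labels)
  plan <- new("SplitPlan", trainIds = seq_len(n), testIds = integer(0),
              folds = list(), labels = labels, seed = 1L)
  plan <- makeFolds(plan, 5L)
  expect_equal(vapply(plan@folds, function(f) length(f$train), integer(1)),
               rep(1608L, 5L))
  expect_equal(vapply(plan@folds, function(f) length(f$val), integer(1)),
               rep(402L, 5L))
})

test_that("split plans survive a JSON round trip", {
  idx <- indexDataset(synthFixture())
  plan <- makeFolds(makeSplit(idx, 0.3, seed = 6L), 2L)
  path <- file.path(tempdir(), "plan-rt.json")
  writeSplitPlan(plan, path)
  back <- readSplitPlan(path)
  expect_identical(back@trainIds, plan@trainIds)
  expect_identical(back@testIds, plan@testIds)
  expect_identical(back@seed, plan@seed)
  expect_equal(back@folds, plan@folds)
})

test_that("preprocessing swaps RGB to BGR and zero-centres on the means", {
  const <- array(0, c(4, 4, 3))
  const[, , 1] <- 123.68; const[, , 2] <- 116.779; const[, , 3] <- 103.939
  expect_equal(max(abs(preprocessImages(const))), 0)
  red <- array(0, c(2, 2, 3)); red[, , 1] <- 200
  out <- preprocessImages(red)
  expect_equal(out[1, 1, 3], 200 - 123.68)           # red lands in channel 3
  expect_equal(out[1, 1, 1], -103.939)               # blue channel centred
  x <- randomImageBatch(2, 8)
  expect_equal(unpreprocessImages(preprocessImages(x)), x, tolerance = 1e-12)
  expect_error(preprocessImages(array(0, c(2, 4, 4, 2))), "3-channel")
})

test_that("augmentation at zero magnitudes is the identity and crops to size", {
  img <- array(randomImageBatch(1, 64)[1, , , ], c(64, 64, 3))
  expect_identical(augmentImage(img, identityAugment(64L), seed = 2L), img)
  out <- augmentImage(img, augmentConfig(cropSize = 56L), seed = 3L)
  expect_equal(dim(out), c(56L, 56L, 3L))
  expect_identical(out, augmentImage(img, augmentConfig(cropSize = 56L),
                                     seed = 3L))
  expect_false(identical(out, augmentImage(img, augmentConfig(cropSize = 56L),
                                           seed = 4L)))
  expect_error(augmentImage(img, augmentConfig(cropSize = 128L)), "crop size")
})
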