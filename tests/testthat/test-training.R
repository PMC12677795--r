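# Training tests run at 32x32 with widthMultiplier 1/16 to stay fast; the
# full-scale end-to-end criterion lives in test-acceptance.R.

smallConfig <- function(epochs = 3L, seed = 11L) {
  trainConfig(epochs = epochs, folds = 2L, batchSize = 4L,
              widthMultiplier = 1 / 16, seed = seed)
}

smallPhantoms <- function(n, seed = 11L) {
  makePhantomDataset(phantomConfig(size = 32, radiusRange = c(4, 7),
                                   seed = seed), n)
}

test_that("trainConfig validates and round-trips through YAML", {
  cfg <- trainConfig(epochs = 5, loss = "dice", widthMultiplier = 1 / 8)
  expect_s3_class(cfg, "TrainConfig")
  expect_error(trainConfig(epochs = 0), "epochs")
  expect_error(trainConfig(folds = 1), "folds")
  expect_error(trainConfig(batchSize = 0), "batchSize")
  expect_error(trainConfig(loss = "mse"))
  f <- tempfile(fileext = ".yaml")
  writeTrainConfig(cfg, f)
  expect_identical(readTrainConfig(f), cfg)
  unlink(f)
})

test_that("training reduces the loss and records a history", {
  pairs <- smallPhantoms(8)
  fit <- trainModel(pairs, smallConfig(epochs = 4))
  h <- fit$history
  expect_identical(names(h), c("epoch", "train_loss"))
  expect_identical(nrow(h), 4L)
  expect_lt(h$train_loss[4], h$train_loss[1])
  expect_s4_class(fit$model, "UNetModel")
})

test_that("validation loss is tracked when held-out pairs are supplied", {
  pairs <- smallPhantoms(8)
  fit <- trainModel(pairs[1:6], smallConfig(epochs = 2),
                    validationPairs = pairs[7:8])
  expect_true("val_loss" %in% names(fit$history))
  expect_true(all(is.finite(fit$history$val_loss)))
})

test_that("training is deterministic given the config seed", {
  pairs <- smallPhantoms(6)
  f1 <- trainModel(pairs, smallConfig(epochs = 2, seed = 3))
  f2 <- trainModel(pairs, smallConfig(epochs = 2, seed = 3))
  expect_equal(f1$history$train_loss, f2$history$train_loss,
               tolerance = 1e-12)
  expect_identical(f1$model@weights, f2$model@weights)
  f3 <- trainModel(pairs, smallConfig(epochs = 2, seed = 4))
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("alternative losses train and decrease", {
  pairs <- smallPhantoms(6)
  for (loss in c("dice", "bce_plus_dice")) {
    cfg <- trainConfig(epochs = 3, folds = 2, batchSize = 4, loss = loss,
                       widthMultiplier = 1 / 16, seed = 11)
    h <- trainModel(pairs, cfg)$history
    expect_lt(h$train_loss[3], h$train_loss[1])
  }
})

test_that("trainModel validates its inputs", {
  pairs <- smallPhantoms(4)
  expect_error(trainModel(pairs[1], smallConfig()), "at least 2")
  noMask <- imagePair(mri(pairs[[1]]), pet(pairs[[1]]), id = "nomask")
  expect_error(trainModel(list(noMask, pairs[[2]]), smallConfig()),
               "no ground-truth mask")
})

test_that("predictMask returns a scored SegmentationResult", {
  pairs <- smallPhantoms(6)
  fit <- trainModel(pairs, smallConfig(epochs = 2))
  res <- predictMask(fit$model, pairs[[1]])
  expect_s4_class(res, "SegmentationResult")
  p <- probabilityMap(res)
  expect_identical(dim(p), c(32L, 32L))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(binaryMask(res), binarize(p, 0.5))
  expect_true(res@dice >= 0 && res@dice <= 1)
  expect_equal(res@iou, res@dice / (2 - res@dice), tolerance = 1e-12)
  # a pair without a mask predicts but reports NA metrics
  bare <- imagePair(mri(pairs[[1]]), pet(pairs[[1]]), id = "bare")
  resB <- predictMask(fit$model, bare)
  expect_true(is.na(resB@dice))
  # self-consistency: using the prediction as truth gives Dice 1
  self <- imagePair(mri(pairs[[1]]), pet(pairs[[1]]),
                    mask = binaryMask(res), id = "self")
  expect_equal(suppressWarnings(predictMask(fit$model, self)@dice), 1)
})

test_that("crossValidate partitions the data and averages fold metrics", {
  pairs <- smallPhantoms(6)
  cfg <- smallConfig(epochs = 1)
  cv <- crossValidate(pairs, cfg)
  expect_length(cv$folds, 2)
  allIds <- unlist(lapply(cv$folds, `[[`, "ids"))
  expect_setequal(allIds, vapply(pairs, imageId, character(1)))
  expect_false(anyDuplicated(allIds) > 0)
  # summary is the arithmetic mean of per-fold values
  for (m in c("dice", "iou", "accuracy")) {
    expect_equal(cv$summary[[m]],
                 mean(vapply(cv$folds, `[[`, numeric(1), m)),
                 tolerance = 1e-12)
  }
  # deterministic fold assignment and metrics
  cv2 <- crossValidate(pairs, cfg)
  expect_identical(lapply(cv$folds, `[[`, "ids"),
                   lapply(cv2$folds, `[[`, "ids"))
  expect_equal(cv$summary, cv2$summary, tolerance = 1e-12)
  expect_error(crossValidate(pairs[1:3], trainConfig(folds = 5)),
               "as many samples")
})
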