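## Training harness: fuse -> network pipeline with a seeded Adam loop and
## k-fold cross-validation. All randomness (weight init, shuffling) is drawn
## on the R side from the config seed; the C++ engine is deterministic, so
## identical configs reproduce identical losses.

#' Construct a training configuration
#'
#' The loss defaults to binary cross-entropy, which matches the sigmoid
#' single-channel head; a soft Dice loss and their sum are selectable.
#' Optimiser is Adam (beta1 0.9, beta2 0.999, eps 1e-8) with learning rate
#' 1e-3 by default.
#'
#' @param epochs training epochs, >= 1.
#' @param folds cross-validation fold count, >= 2.
#' @param batchSize minibatch size, >= 1.
#' @param learningRate Adam step size.
#' @param loss `"bce"`, `"dice"` or `"bce_plus_dice"`.
#' @param seed integer seed driving init and shuffling.
#' @param widthMultiplier network width scaling (see [networkSpec()]).
#' @param threshold binarisation threshold for predicted masks.
#' @param fusionMode fusion rule fed to [fusePair()] ahead of the network.
#' @return A list of class `TrainConfig`.
#' @examples
#' trainConfig(epochs = 5, widthMultiplier = 1/16)
#' @export
trainConfig <- function(epochs = 100L, folds = 5L, batchSize = 8L,
                        learningRate = 1e-3,
                        loss = c("bce", "dice", "bce_plus_dice"), seed = 1L,
                        widthMultiplier = 1, threshold = 0.5,
                        fusionMode = "paper_reconstruct") {
  loss <- match.arg(loss)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (folds < 2L) stop("folds must be >= 2")
  if (batchSize < 1L) stop("batchSize must be >= 1")
  structure(list(epochs = as.integer(epochs), folds = as.integer(folds),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, loss = loss,
                 seed = as.integer(seed), widthMultiplier = widthMultiplier,
                 threshold = threshold, fusionMode = fusionMode),
            class = "TrainConfig")
}

#' Read/write a TrainConfig as a flat YAML document
#'
#' @param path YAML file with keys mirroring [trainConfig()] arguments.
#' @return A `TrainConfig`.
#' @export
readTrainConfig <- function(path) {
  do.call(trainConfig, yaml::read_yaml(path))
}

#' @rdname readTrainConfig
#' @param config a `TrainConfig`.
#' @export
writeTrainConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

fusePairs <- function(pairs, mode) {
  lapply(pairs, function(p) fusePair(p, mode)@pixels)
}

checkTrainingPairs <- function(pairs) {
  if (length(pairs) < 2L) stop("need at least 2 training pairs")
  for (p in pairs) {
    if (is.null(p@mask)) stop("pair '", p@id, "' has no ground-truth mask")
    if (!all(p@mask %in% c(0, 1)))
      stop("pair '", p@id, "' has a non-binary mask")
  }
}

## One Adam step over the named gradient list; state carries m, v, t.
adamStep <- function(weights, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (n in names(grads)) {
    g <- grads[[n]]
    if (is.null(state$m[[n]])) {
      state$m[[n]] <- g * 0
      state$v[[n]] <- g * 0
    }
    state$m[[n]] <- beta1 * state$m[[n]] + (1 - beta1) * g
    state$v[[n]] <- beta2 * state$v[[n]] + (1 - beta2) * g^2
    weights[[n]] <- weights[[n]] -
      lr * (state$m[[n]] / corr1) / (sqrt(state$v[[n]] / corr2) + eps)
  }
  list(weights = weights, state = state)
}

bceLoss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the segmentation network on fused image pairs
#'
#' Runs the fuse-then-segment pipeline: every pair is fused with the
#' config's fusion rule, replicated to the network's input channels, and
#' the network is trained with seeded Adam on the config's loss. The run is
#' deterministic given the config: weight initialisation and epoch shuffles
#' derive from `config$seed`.
#'
#' @param pairs list of [ImagePair-class] objects with binary masks.
#' @param config a [trainConfig()].
#' @param validationPairs optional held-out pairs; their BCE loss is tracked
#'   per epoch.
#' @param verbose print per-epoch losses.
#' @return List with `model` ([UNetModel-class]) and `history` (data.frame
#'   of per-epoch `train_loss` and, if tracked, `val_loss`).
#' @export
trainModel <- function(pairs, config, validationPairs = NULL,
                       verbose = FALSE) {
  checkTrainingPairs(pairs)
  d <- dim(pairs[[1]]@mri)
  spec <- networkSpec(inputH = d[1], inputW = d[2], inputChannels = 3L,
                      widthMultiplier = config$widthMultiplier)
  xs <- fusePairs(pairs, config$fusionMode)
  ys <- lapply(pairs, tumourMask)
  valXs <- if (!is.null(validationPairs))
    fusePairs(validationPairs, config$fusionMode)

  model <- buildNetwork(spec, seed = config$seed)
  a <- cppChannelArgs(spec)
  xs <- lapply(xs, asNetworkInput, spec = spec)
  state <- list(m = list(), v = list(), t = 0L)
  n <- length(xs)
  hist <- vector("list", config$epochs)

  withLocalSeed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
      lossSum <- 0
      for (bi in batches) {
        res <- cpp_unet_train(model@weights, xs[bi], ys[bi], a$encC, a$midC,
                              a$plan, a$inC, config$loss, 0.1)
        for (rn in names(res$running)) model@weights[[rn]] <- res$running[[rn]]
        upd <- adamStep(model@weights, res$grads, state, config$learningRate)
        model@weights <- upd$weights
        state <- upd$state
        lossSum <- lossSum + res$loss * length(bi)
      }
      row <- data.frame(epoch = epoch, train_loss = lossSum / n)
      if (!is.null(validationPairs)) {
        probs <- unetForward(model, valXs)
        row$val_loss <- mean(mapply(function(p, vp) bceLoss(p, vp@mask),
                                    probs, validationPairs))
      }
      hist[[epoch]] <- row
      if (verbose)
        message(sprintf("epoch %d: %s", epoch,
                        paste(sprintf("%s=%.4f", names(row)[-1],
                                      unlist(row[-1])), collapse = " ")))
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

#' Segment one pair with a trained model
#'
#' Fuses the pair, runs the network in inference mode, binarises the
#' probability map, and scores Dice/IoU/pixel accuracy when the pair carries
#' a ground-truth mask.
#'
#' @param model a trained [UNetModel-class].
#' @param pair an [ImagePair-class].
#' @param mode fusion rule (should match the one used in training).
#' @param threshold binarisation threshold.
#' @return A [SegmentationResult-class].
#' @export
predictMask <- function(model, pair, mode = "paper_reconstruct",
                        threshold = 0.5) {
  fused <- fusePair(pair, mode)@pixels
  prob <- unetForward(model, fused)
  msk <- binarize(prob, threshold)
  if (!is.null(pair@mask)) {
    new("SegmentationResult", prob = prob, mask = msk,
        dice = diceCoef(msk, pair@mask), iou = iou(msk, pair@mask),
        accuracy = pixelAccuracy(msk, pair@mask), id = pair@id)
  } else {
    new("SegmentationResult", prob = prob, mask = msk, dice = NA_real_,
        iou = NA_real_, accuracy = NA_real_, id = pair@id)
  }
}

#' k-fold cross-validation of the fuse-then-segment pipeline
#'
#' Seeded shuffle into `config$folds` disjoint folds covering all pairs;
#' each fold in turn is held out, the model is trained on the rest, and
#' Dice/IoU/accuracy are averaged over the fold's validation pairs.
#'
#' @param pairs list of [ImagePair-class] objects with masks.
#' @param config a [trainConfig()].
#' @param verbose print per-fold progress.
#' @return List with `folds` (per-fold list: `fold`, `history`, `dice`,
#'   `iou`, `accuracy`, `ids`) and `summary` (metric means across folds).
#' @export
crossValidate <- function(pairs, config, verbose = FALSE) {
  n <- length(pairs)
  if (n < config$folds)
    stop("need at least as many samples (", n, ") as folds (", config$folds, ")")
  assign <- withLocalSeed(config$seed, {
    idx <- sample(n)
    split(idx, cut(seq_along(idx), config$folds, labels = FALSE))
  })
  foldResults <- lapply(seq_along(assign), function(k) {
    valIdx <- assign[[k]]
    fit <- trainModel(pairs[-valIdx], config, verbose = FALSE)
    res <- lapply(pairs[valIdx], function(p)
      predictMask(fit$model, p, mode = config$fusionMode,
                  threshold = config$threshold))
    if (verbose) message("fold ", k, " done")
    list(fold = k, history = fit$history,
         dice = mean(vapply(res, function(r) r@dice, numeric(1))),
         iou = mean(vapply(res, function(r) r@iou, numeric(1))),
         accuracy = mean(vapply(res, function(r) r@accuracy, numeric(1))),
         ids = vapply(pairs[valIdx], imageId, character(1)))
  })
  list(folds = foldResults,
       summary = list(
         dice = mean(vapply(foldResults, `[[`, numeric(1), "dice")),
         iou = mean(vapply(foldResults, `[[`, numeric(1), "iou")),
         accuracy = mean(vapply(foldResults, `[[`, numeric(1), "accuracy"))))
}
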