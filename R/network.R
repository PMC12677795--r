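## The five-level encoder-decoder segmentation network.
##
## Encoder block i: [2x2 stride-2 max pool, blocks 2-5] -> 3x3 conv -> ReLU
## -> 3x3 conv -> batch norm -> ReLU, with filter counts doubling 64 ... 1024
## at full width. Middle: pool -> conv(2048) -> ReLU -> conv(2048) -> BN ->
## ReLU on the 8x8 grid (for 256x256 input). Decoder block j: 2x2 stride-2
## transpose conv -> concatenate the matching encoder skip -> 3x3 conv ->
## ReLU -> 3x3 conv -> BN -> ReLU, with the channel plan below; head: 1x1
## conv -> sigmoid. All convolutions are biased and 'same'-padded. The
## decoder channel plan is the unique one under which every published
## per-layer parameter count satisfies kernel^2 * in * out + out and the
## trainable total of 122,480,513 is recovered exactly.

#' Construct a network specification
#'
#' @param inputH,inputW input dims in pixels; must be divisible by 32 (five
#'   2x2 stride-2 poolings reach the middle grid).
#' @param inputChannels input channel count; grayscale fused images are
#'   replicated to this many channels (default 3).
#' @param baseFilters encoder level-1 filter count at full width.
#' @param middleFilters bottleneck filter count at full width.
#' @param widthMultiplier positive rational scaling every filter count;
#'   scaled counts must be positive integers (e.g. 1/16, 1/8, 1).
#' @return A [NetworkSpec-class].
#' @examples
#' networkSpec()                       # the full-width architecture
#' networkSpec(64, 64, widthMultiplier = 1/8)  # desk-scale variant
#' @export
networkSpec <- function(inputH = 256L, inputW = 256L, inputChannels = 3L,
                        baseFilters = 64L, middleFilters = 2048L,
                        widthMultiplier = 1) {
  new("NetworkSpec", inputH = as.integer(inputH), inputW = as.integer(inputW),
      inputChannels = as.integer(inputChannels),
      baseFilters = as.integer(baseFilters),
      middleFilters = as.integer(middleFilters), depth = 5L,
      convKernel = 3L, transposeKernel = 2L, finalKernel = 1L,
      widthMultiplier = widthMultiplier)
}

## Scaled encoder/middle channel counts.
encoderChannels <- function(spec) {
  as.integer(round(spec@baseFilters * 2^(0:4) * spec@widthMultiplier))
}
middleChannels <- function(spec) {
  as.integer(round(spec@middleFilters * spec@widthMultiplier))
}

#' Decoder channel plan
#'
#' Per decoder block: transpose-conv input and output channels and the two
#' subsequent conv output channels (`conv1` consumes transpose output plus
#' the concatenated encoder skip). At full width:
#' (2048 -> 1024, 1024, 1024), (1024 -> 512, 512, 256), (256 -> 256, 256,
#' 128), (128 -> 128, 128, 64), (64 -> 64, 64, 64) -- transpose convs
#' preserve channels in blocks 3-5 and conv2 halves them in blocks 2-4.
#'
#' @param spec a [NetworkSpec-class].
#' @return data.frame with columns `block`, `transposeIn`, `transposeOut`,
#'   `conv1In`, `conv1Out`, `conv2Out`.
#' @export
channelPlan <- function(spec) {
  enc <- encoderChannels(spec)
  transposeOut <- rev(enc)                                # 1024 ... 64
  conv1Out <- rev(enc)
  conv2Out <- c(enc[5], enc[4] %/% 2L, enc[3] %/% 2L, enc[2] %/% 2L, enc[1])
  transposeIn <- c(middleChannels(spec), conv2Out[1:4])
  skip <- rev(enc)
  data.frame(block = 1:5, transposeIn = transposeIn,
             transposeOut = transposeOut, conv1In = transposeOut + skip,
             conv1Out = conv1Out, conv2Out = conv2Out)
}

#' Parameter count of a biased 2-D convolution
#'
#' `kernel^2 * inCh * outCh + outCh` (weights plus one bias per filter).
#'
#' @param inCh,outCh,kernel positive integers.
#' @return Parameter count.
#' @examples
#' conv2dParamCount(3, 64, 3)  # 1792
#' @export
conv2dParamCount <- function(inCh, outCh, kernel) {
  if (inCh < 1 || outCh < 1 || kernel < 1)
    stop("channel and kernel counts must be positive")
  kernel^2 * inCh * outCh + outCh
}

#' Parameter count of a biased transpose convolution
#'
#' Same form as [conv2dParamCount()]: `kernel^2 * inCh * outCh + outCh`.
#'
#' @inheritParams conv2dParamCount
#' @return Parameter count.
#' @examples
#' transposeConvParamCount(2048, 1024, 2)  # 8389632
#' @export
transposeConvParamCount <- function(inCh, outCh, kernel) {
  conv2dParamCount(inCh, outCh, kernel)
}

#' Parameter counts of a batch-normalisation layer
#'
#' Four parameters per channel in total (scale, shift, running mean, running
#' variance), of which scale and shift are trainable.
#'
#' @param channels positive integer.
#' @return Named vector `c(total, trainable)`.
#' @examples
#' batchNormParamCount(2048)  # total 8192, trainable 4096
#' @export
batchNormParamCount <- function(channels) {
  if (channels < 1) stop("channels must be >= 1")
  c(total = 4 * channels, trainable = 2 * channels)
}

shapeStr <- function(h, w, c) sprintf("%dx%dx%d", h, w, c)

#' Per-layer report of the network
#'
#' The machine twin of the published layer table: one row per layer in
#' forward order (including zero-parameter pooling, activation and
#' concatenation rows), with consistently chained input/output shapes and
#' analytic parameter counts.
#'
#' @param spec a [NetworkSpec-class].
#' @return data.frame with columns `block`, `layer`, `input_shape`,
#'   `filters`, `output_shape`, `params`, `trainable`.
#' @export
layerReport <- function(spec) {
  validObject(spec)
  enc <- encoderChannels(spec)
  mid <- middleChannels(spec)
  plan <- channelPlan(spec)
  k <- spec@convKernel; tk <- spec@transposeKernel
  rows <- list()
  add <- function(block, layer, h, w, cin, filters, ho, wo, cout, params,
                  trainable = params) {
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, layer = layer, input_shape = shapeStr(h, w, cin),
      filters = filters, output_shape = shapeStr(ho, wo, cout),
      params = params, trainable = trainable)
  }
  H <- spec@inputH; W <- spec@inputW; C <- spec@inputChannels
  add("Down Sampling Block-1", "Input", H, W, C, NA, H, W, C, 0)
  for (i in 1:5) {
    blk <- sprintf("Down Sampling Block-%d", i)
    if (i > 1) {
      add(blk, "MaxPooling", H, W, C, C, H / 2, W / 2, C, 0)
      H <- H / 2; W <- W / 2
    }
    add(blk, "Conv2D", H, W, C, enc[i], H, W, enc[i],
        conv2dParamCount(C, enc[i], k))
    add(blk, "Activation", H, W, enc[i], NA, H, W, enc[i], 0)
    add(blk, "Conv2D", H, W, enc[i], enc[i], H, W, enc[i],
        conv2dParamCount(enc[i], enc[i], k))
    bn <- batchNormParamCount(enc[i])
    add(blk, "BatchNormalization", H, W, enc[i], NA, H, W, enc[i],
        bn["total"], bn["trainable"])
    add(blk, "Activation", H, W, enc[i], NA, H, W, enc[i], 0)
    C <- enc[i]
  }
  add("Middle Layer", "MaxPooling", H, W, C, C, H / 2, W / 2, C, 0)
  H <- H / 2; W <- W / 2
  add("Middle Layer", "Conv2D", H, W, C, mid, H, W, mid,
      conv2dParamCount(C, mid, k))
  add("Middle Layer", "Activation", H, W, mid, NA, H, W, mid, 0)
  add("Middle Layer", "Conv2D", H, W, mid, mid, H, W, mid,
      conv2dParamCount(mid, mid, k))
  bn <- batchNormParamCount(mid)
  add("Middle Layer", "BatchNormalization", H, W, mid, NA, H, W, mid,
      bn["total"], bn["trainable"])
  add("Middle Layer", "Activation", H, W, mid, NA, H, W, mid, 0)
  C <- mid
  for (j in 1:5) {
    blk <- sprintf("Up Sampling Block-%d", j)
    p <- plan[j, ]
    add(blk, "Conv2DTranspose", H, W, p$transposeIn, p$transposeOut,
        H * 2, W * 2, p$transposeOut,
        transposeConvParamCount(p$transposeIn, p$transposeOut, tk))
    H <- H * 2; W <- W * 2
    add(blk, "Concatenate", H, W, p$transposeOut, NA, H, W, p$conv1In, 0)
    add(blk, "Conv2D", H, W, p$conv1In, p$conv1Out, H, W, p$conv1Out,
        conv2dParamCount(p$conv1In, p$conv1Out, k))
    add(blk, "Activation", H, W, p$conv1Out, NA, H, W, p$conv1Out, 0)
    add(blk, "Conv2D", H, W, p$conv1Out, p$conv2Out, H, W, p$conv2Out,
        conv2dParamCount(p$conv1Out, p$conv2Out, k))
    bn <- batchNormParamCount(p$conv2Out)
    add(blk, "BatchNormalization", H, W, p$conv2Out, NA, H, W, p$conv2Out,
        bn["total"], bn["trainable"])
    add(blk, "Activation", H, W, p$conv2Out, NA, H, W, p$conv2Out, 0)
    C <- p$conv2Out
  }
  add("Output", "Conv2D", H, W, C, 1, H, W, 1,
      conv2dParamCount(C, 1, spec@finalKernel))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count network parameters analytically
#'
#' Sums the per-layer report. At full width the trainable total is
#' 122,480,513 and the total exceeds it by twice the batch-norm channel sum
#' (2 x 5568 = 11,136 running statistics).
#'
#' @param spec a [NetworkSpec-class].
#' @return List with `total`, `trainable` and the per-layer `report`.
#' @examples
#' countParameters(networkSpec())$trainable  # 122480513
#' @export
countParameters <- function(spec) {
  rep <- layerReport(spec)
  list(total = sum(rep$params), trainable = sum(rep$trainable), report = rep)
}

heInit <- function(nOut, nIn, fanIn) {
  matrix(rnorm(nOut * nIn, sd = sqrt(2 / fanIn)), nOut, nIn)
}

#' Build the network
#'
#' Creates the named weight list in canonical layer order. Convolution
#' kernels are stored as `out x (in * k^2)` matrices (transpose kernels as
#' `(out * k^2) x in`), biases as vectors, batch norm as per-channel scale
#' (1), shift (0), running mean (0) and running variance (1). He-normal
#' initialisation by default (`sd = sqrt(2 / fan_in)`), seeded; `"zeros"`
#' allocates without randomness (useful for shape/count introspection).
#'
#' @param spec a [NetworkSpec-class].
#' @param seed integer seed for the initialisation.
#' @param init `"he"` or `"zeros"`.
#' @return A [UNetModel-class].
#' @export
buildNetwork <- function(spec, seed = 1L, init = c("he", "zeros")) {
  validObject(spec)
  init <- match.arg(init)
  enc <- encoderChannels(spec)
  mid <- middleChannels(spec)
  plan <- channelPlan(spec)
  k <- spec@convKernel; tk <- spec@transposeKernel
  w <- list()
  mk <- function(nOut, nIn, fanIn) {
    if (init == "zeros") matrix(0, nOut, nIn) else heInit(nOut, nIn, fanIn)
  }
  buildAll <- function() {
    addConv <- function(name, cin, cout, kk) {
      w[[paste0(name, "_W")]] <<- mk(cout, cin * kk^2, cin * kk^2)
      w[[paste0(name, "_b")]] <<- numeric(cout)
    }
    addTconv <- function(name, cin, cout, kk) {
      w[[paste0(name, "_W")]] <<- mk(cout * kk^2, cin, cin * kk^2)
      w[[paste0(name, "_b")]] <<- numeric(cout)
    }
    addBN <- function(name, ch) {
      w[[paste0(name, "_g")]] <<- rep(1, ch)
      w[[paste0(name, "_b")]] <<- numeric(ch)
      w[[paste0(name, "_rm")]] <<- numeric(ch)
      w[[paste0(name, "_rv")]] <<- rep(1, ch)
    }
    C <- spec@inputChannels
    for (i in 1:5) {
      addConv(sprintf("enc%d_c1", i), C, enc[i], k)
      addConv(sprintf("enc%d_c2", i), enc[i], enc[i], k)
      addBN(sprintf("enc%d_bn", i), enc[i])
      C <- enc[i]
    }
    addConv("mid_c1", C, mid, k)
    addConv("mid_c2", mid, mid, k)
    addBN("mid_bn", mid)
    for (j in 1:5) {
      p <- plan[j, ]
      addTconv(sprintf("dec%d_up", j), p$transposeIn, p$transposeOut, tk)
      addConv(sprintf("dec%d_c1", j), p$conv1In, p$conv1Out, k)
      addConv(sprintf("dec%d_c2", j), p$conv1Out, p$conv2Out, k)
      addBN(sprintf("dec%d_bn", j), p$conv2Out)
    }
    addConv("head", plan$conv2Out[5], 1L, spec@finalKernel)
  }
  if (init == "he") withLocalSeed(seed, buildAll()) else buildAll()
  new("UNetModel", spec = spec, weights = w)
}

#' Introspect parameter counts of a built model
#'
#' Counts the elements of the weight arrays actually allocated; batch-norm
#' running statistics (`_rm`, `_rv`) are the non-trainable part. This is the
#' independent cross-check of [countParameters()].
#'
#' @param model a [UNetModel-class].
#' @return Named vector `c(total, trainable)`.
#' @export
countModelParameters <- function(model) {
  n <- vapply(model@weights, length, numeric(1))
  running <- grepl("_(rm|rv)$", names(n))
  c(total = sum(n), trainable = sum(n[!running]))
}

## Replicate a grayscale matrix (or pass through an array) to the channel
## count the spec expects, as an H x W x C array.
asNetworkInput <- function(x, spec) {
  if (is.matrix(x)) x <- array(rep(x, spec@inputChannels),
                               dim = c(dim(x), spec@inputChannels))
  if (!identical(dim(x)[1:2], c(spec@inputH, spec@inputW)) ||
      dim(x)[3] != spec@inputChannels)
    stop("input shape ", paste(dim(x), collapse = "x"),
         " does not match the spec (", spec@inputH, "x", spec@inputW, "x",
         spec@inputChannels, ")")
  x
}

cppChannelArgs <- function(spec) {
  plan <- channelPlan(spec)
  list(encC = encoderChannels(spec), midC = middleChannels(spec),
       plan = as.matrix(plan[, c("transposeIn", "transposeOut", "conv1In",
                                 "conv1Out", "conv2Out")]),
       inC = spec@inputChannels)
}

#' Forward pass
#'
#' Runs the network in inference mode (batch norm uses running statistics)
#' on one image or a list of images; grayscale matrices are replicated to
#' the spec's channel count.
#'
#' @param model a [UNetModel-class].
#' @param x matrix, H x W x C array, or list thereof.
#' @return Probability map matrix in `[0, 1]` (list thereof for list input).
#' @export
unetForward <- function(model, x) {
  single <- !is.list(x)
  if (single) x <- list(x)
  xs <- lapply(x, asNetworkInput, spec = model@spec)
  a <- cppChannelArgs(model@spec)
  out <- cpp_unet_predict(model@weights, xs, a$encC, a$midC, a$plan, a$inC)
  if (single) out[[1]] else out
}
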