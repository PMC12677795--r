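## Preprocessing: resizing, intensity normalisation, seeded augmentation and
## the train/test split.

#' Resize an image
#'
#' Bilinear interpolation for intensity images; nearest-neighbour for masks,
#' which preserves binarity. Intensity output is clamped to the input's
#' range (bit-depth range for [RawImage-class] inputs).
#'
#' @param img a [RawImage-class] or plain numeric matrix.
#' @param targetH,targetW target dims in pixels, >= 1.
#' @param mask logical; treat the image as a binary mask and use
#'   nearest-neighbour interpolation.
#' @return Same type as `img`, resized to `targetH x targetW`.
#' @examples
#' dim(resizeImage(matrix(runif(220 * 220), 220, 220), 256, 256))
#' @export
resizeImage <- function(img, targetH, targetW, mask = FALSE) {
  if (targetH < 1 || targetW < 1)
    stop("target dimensions must be positive (got ", targetH, "x", targetW, ")")
  raw <- is(img, "RawImage")
  px <- if (raw) img@pixels else img
  if (identical(dim(px), c(as.integer(targetH), as.integer(targetW))))
    return(img)
  out <- as.matrix(EBImage::resize(px, w = targetH, h = targetW,
                                   filter = if (mask) "none" else "bilinear"))
  if (raw) {
    out <- pmin(pmax(out, 0), 2^img@bitDepth - 1)
    rawImage(out, img@bitDepth)
  } else {
    pmin(pmax(out, min(px)), max(px))
  }
}

#' Normalise image intensities to unit range
#'
#' Two divisor conventions are provided. `paper_literal` divides by
#' `2^bitDepth` (256 for 8-bit images), so the maximum intensity maps to
#' 255/256; `max_value` divides by `2^bitDepth - 1` (255, 4095 or 65535), so
#' the maximum maps exactly to 1. The literal convention is the default.
#'
#' @param img a [RawImage-class].
#' @param mode `"paper_literal"` or `"max_value"`.
#' @return Numeric matrix with values in `[0, 1]`.
#' @examples
#' normalizeIntensity(rawImage(matrix(128, 1, 1), 8))  # 0.5
#' @export
normalizeIntensity <- function(img, mode = c("paper_literal", "max_value")) {
  mode <- match.arg(mode)
  if (!is(img, "RawImage")) stop("img must be a RawImage")
  divisor <- if (mode == "paper_literal") 2^img@bitDepth else 2^img@bitDepth - 1
  img@pixels / divisor
}

## Uniformly sample one transform from the augmentation menu.
sampleTransform <- function() {
  type <- sample(c("rotate", "flip", "flop", "zoom", "brightness", "shift"), 1)
  switch(type,
    rotate = list(type = "rotate", angle = runif(1, -15, 15)),
    flip = list(type = "flip"),
    flop = list(type = "flop"),
    zoom = list(type = "zoom", factor = runif(1, 0.9, 1.1)),
    brightness = list(type = "brightness", factor = runif(1, 0.9, 1.1)),
    shift = list(type = "shift",
                 dx = sample(-10:10, 1), dy = sample(-10:10, 1)))
}

## Zoom by resampling to round(S * factor) then centre-cropping or
## zero-padding back to the original dims.
zoomMatrix <- function(px, factor, mask) {
  d <- dim(px)
  nd <- pmax(round(d * factor), 1)
  z <- as.matrix(EBImage::resize(px, w = nd[1], h = nd[2],
                                 filter = if (mask) "none" else "bilinear"))
  out <- matrix(0, d[1], d[2])
  oi <- pmax(floor((d - nd) / 2), 0)    # offset into out (pad) ...
  zi <- pmax(floor((nd - d) / 2), 0)    # ... or into z (crop)
  n <- pmin(d, nd)
  out[oi[1] + seq_len(n[1]), oi[2] + seq_len(n[2])] <-
    z[zi[1] + seq_len(n[1]), zi[2] + seq_len(n[2])]
  out
}

#' Apply a recorded augmentation transform to a single image
#'
#' The same transform record drives the MRI channel, the PET channel and the
#' mask of an augmented pair, which is what keeps augmented pairs
#' co-registered. With `mask = TRUE`, geometric transforms use
#' nearest-neighbour resampling, the result is re-binarised at 0.5, and
#' intensity-only transforms (brightness) are the identity.
#'
#' @param px numeric matrix (unit-range image or 0/1 mask).
#' @param transform a transform record as produced by [augmentDataset()]
#'   (list with `type` and its parameters).
#' @param mask logical; treat `px` as a binary mask.
#' @return Transformed matrix with the same dims.
#' @export
applyTransform <- function(px, transform, mask = FALSE) {
  filt <- if (mask) "none" else "bilinear"
  out <- switch(transform$type,
    rotate = as.matrix(EBImage::rotate(px, transform$angle, filter = filt,
                                       output.dim = dim(px), bg.col = 0)),
    flip = as.matrix(EBImage::flip(px)),
    flop = as.matrix(EBImage::flop(px)),
    zoom = zoomMatrix(px, transform$factor, mask),
    brightness = if (mask) px else px * transform$factor,
    shift = as.matrix(EBImage::translate(px, c(transform$dx, transform$dy),
                                         bg.col = 0)),
    stop("unknown transform type: ", transform$type))
  out <- pmin(pmax(out, 0), 1)
  if (mask) out <- (out >= 0.5) + 0
  out
}

#' Augment a dataset of image pairs to a target size
#'
#' The originals are retained unchanged; each additional pair is a randomly
#' chosen original under one transform drawn uniformly from the menu:
#' rotation (+-15 deg), horizontal/vertical flip, zoom (0.9-1.1), brightness
#' scaling (0.9-1.1), and integer shifts (+-10 px). The identical transform
#' is applied to MRI, PET and mask, and is recorded in the new pair's
#' `transform` slot. Deterministic given `seed`.
#'
#' @param pairs list of [ImagePair-class] objects.
#' @param targetN desired output count, >= `length(pairs)`.
#' @param seed integer seed.
#' @return List of `targetN` [ImagePair-class] objects.
#' @export
augmentDataset <- function(pairs, targetN, seed = 1L) {
  n <- length(pairs)
  if (targetN < n)
    stop("targetN (", targetN, ") must be at least the input count (", n, ")")
  if (targetN == n) return(pairs)
  withLocalSeed(seed, {
    extra <- lapply(seq_len(targetN - n), function(i) {
      src <- pairs[[sample(n, 1)]]
      tr <- sampleTransform()
      msk <- if (!is.null(src@mask)) applyTransform(src@mask, tr, mask = TRUE)
      imagePair(applyTransform(src@mri, tr), applyTransform(src@pet, tr),
                mask = msk, id = sprintf("%s_aug%03d", src@id, i),
                transform = tr)
    })
    c(pairs, extra)
  })
}

#' Split ids into train and test sets
#'
#' Seeded shuffle, then the first `trainN` ids train and the remainder test;
#' the two lists are disjoint and jointly cover the input.
#'
#' @param ids character or integer vector of identifiers.
#' @param trainN number of training ids, `<= length(ids)`.
#' @param seed integer seed.
#' @return List with elements `train` and `test`.
#' @examples
#' splitDataset(sprintf("img%03d", 1:110), 88, seed = 7)
#' @export
splitDataset <- function(ids, trainN, seed = 1L) {
  if (trainN > length(ids))
    stop("trainN (", trainN, ") exceeds the number of ids (", length(ids), ")")
  withLocalSeed(seed, {
    sh <- sample(ids)
    list(train = sh[seq_len(trainN)],
         test = if (trainN < length(ids)) sh[(trainN + 1):length(ids)]
                else ids[0])
  })
}
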