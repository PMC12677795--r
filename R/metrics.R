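## Evaluation metrics: PSNR and SSIM for fusion quality, Dice / IoU / pixel
## accuracy for segmentation overlap, plus probability-map binarisation.

checkSameDims <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("inputs must share dimensions (got ",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")")
}

checkBinary <- function(m, what) {
  if (!all(m %in% c(0, 1))) stop(what, " must be strictly binary (0/1)")
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(maxI^2 / MSE)` in decibels. Identical inputs have zero MSE;
#' by convention the function then returns `Inf` rather than erroring, so
#' fusion reports on degenerate pairs stay well defined.
#'
#' @param ref,test numeric matrices with identical dims.
#' @param maxI peak intensity of the representation (1 for unit-range
#'   images, 255 for 8-bit).
#' @return PSNR in dB (`Inf` when `ref == test`).
#' @examples
#' psnr(matrix(0, 2, 2), matrix(1, 2, 2), maxI = 1)  # 0 dB
#' @export
psnr <- function(ref, test, maxI = 1) {
  checkSameDims(ref, test)
  if (maxI <= 0) stop("maxI must be positive")
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(maxI^2 / mse)
}

## Sums over all w x w windows fully inside x, via the integral image.
## Returns an (H-w+1) x (W-w+1) matrix of window sums.
slidingWindowSums <- function(x, w) {
  s <- apply(rbind(0, x), 2, cumsum)
  s <- t(apply(cbind(0, s), 1, cumsum))
  H <- nrow(x); W <- ncol(x)
  i <- seq_len(H - w + 1L); j <- seq_len(W - w + 1L)
  s[i + w, j + w, drop = FALSE] + s[i, j, drop = FALSE] -
    s[i + w, j, drop = FALSE] - s[i, j + w, drop = FALSE]
}

#' Structural similarity index
#'
#' Mean local SSIM over all fully-interior sliding windows, using uniform
#' square windows and population (1/n) moments. Stabilisers follow the
#' standard convention `Z1 = (0.01 L)^2`, `Z2 = (0.03 L)^2` where `L` is the
#' dynamic range. (The common printed form of the index has a bare `+1`
#' where symmetry of the luminance term requires `Z1`; the symmetric form is
#' implemented.)
#'
#' @param a,b numeric matrices with identical dims.
#' @param window odd window side length, >= 3 and no larger than the image.
#' @param dynamicRange intensity range `L` (1 for unit-range images).
#' @return SSIM in `[-1, 1]`; 1 for identical images.
#' @examples
#' ssim(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8))
#' @export
ssim <- function(a, b, window = 7L, dynamicRange = 1) {
  checkSameDims(a, b)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3")
  if (window > min(dim(a)))
    stop("window larger than image")
  L <- dynamicRange
  Z1 <- (0.01 * L)^2
  Z2 <- (0.03 * L)^2
  n <- window^2
  muA <- slidingWindowSums(a, window) / n
  muB <- slidingWindowSums(b, window) / n
  varA <- slidingWindowSums(a * a, window) / n - muA^2
  varB <- slidingWindowSums(b * b, window) / n - muB^2
  covAB <- slidingWindowSums(a * b, window) / n - muA * muB
  num <- (2 * muA * muB + Z1) * (2 * covAB + Z2)
  den <- (muA^2 + muB^2 + Z1) * (varA + varB + Z2)
  mean(num / den)
}

#' Dice coefficient
#'
#' Overlap `2|I1 n I2| / (|I1| + |I2|)` between two binary masks, in
#' `[0, 1]`. Two empty masks are scored 1 (vacuous perfect agreement) with a
#' warning, so fold averages over tumour-free slices stay finite.
#'
#' @param i1,i2 binary (0/1) matrices with identical dims.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' diceCoef(matrix(c(1, 1, 1, 0), 2, 2), matrix(c(1, 1, 0, 0), 2, 2))
#' @export
diceCoef <- function(i1, i2) {
  checkSameDims(i1, i2)
  checkBinary(i1, "mask"); checkBinary(i2, "mask")
  s <- sum(i1) + sum(i2)
  if (s == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(i1 * i2) / s
}

#' Intersection over union (Jaccard index)
#'
#' `|I1 n I2| / |I1 u I2|` between two binary masks, in `[0, 1]`; related
#' to Dice by `IoU = DC / (2 - DC)`. Two empty masks are scored 1 with a
#' warning, matching [diceCoef()].
#'
#' @inheritParams diceCoef
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(i1, i2) {
  checkSameDims(i1, i2)
  checkBinary(i1, "mask"); checkBinary(i2, "mask")
  uni <- sum(pmax(i1, i2))
  if (uni == 0) {
    warning("both masks empty; IoU defined as 1")
    return(1)
  }
  sum(i1 * i2) / uni
}

#' Pixel accuracy
#'
#' Fraction of pixels on which prediction and truth agree.
#'
#' @param pred,truth binary (0/1) matrices with identical dims.
#' @return Accuracy in `[0, 1]`.
#' @export
pixelAccuracy <- function(pred, truth) {
  checkSameDims(pred, truth)
  checkBinary(pred, "pred"); checkBinary(truth, "truth")
  mean(pred == truth)
}

#' Binarise a probability map
#'
#' @param prob numeric matrix with values in `[0, 1]`.
#' @param threshold decision threshold in (0, 1); pixels `>= threshold`
#'   become 1.
#' @return Binary matrix of the same dims.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  if (min(prob) < -1e-9 || max(prob) > 1 + 1e-9)
    stop("probability map values must lie in [0, 1]")
  (prob >= threshold) + 0
}
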