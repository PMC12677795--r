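test_that("psnr matches hand-computed values and conventions", {
  # all-zero vs all-one at unit range: MSE 1 -> 0 dB
  expect_equal(psnr(matrix(0, 4, 4), matrix(1, 4, 4), maxI = 1), 0)
  # 8-bit convention: MSE 1 at peak 255 -> 10*log10(255^2) dB
  expect_equal(psnr(matrix(10, 3, 3), matrix(11, 3, 3), maxI = 255),
               10 * log10(255^2))
  expect_equal(round(10 * log10(255^2), 4), 48.1308)
  # identical images -> Inf sentinel, no error
  x <- matrix(runif(25), 5, 5)
  expect_identical(psnr(x, x), Inf)
})

test_that("psnr is symmetric and monotone decreasing in distortion", {
  set.seed(42)
  ref <- matrix(runif(100), 10, 10)
  noisy1 <- ref + 0.01
  noisy2 <- ref + 0.05
  expect_equal(psnr(ref, noisy1), psnr(noisy1, ref))
  expect_gt(psnr(ref, noisy1), psnr(ref, noisy2))
})

test_that("psnr validates its inputs", {
  expect_error(psnr(matrix(0, 2, 2), matrix(0, 2, 3)), "dimensions")
  expect_error(psnr(matrix(0, 2, 2), matrix(0, 2, 2), maxI = 0), "positive")
})

test_that("ssim is 1 for identical images and symmetric", {
  set.seed(7)
  a <- matrix(runif(15 * 12), 15, 12)
  b <- matrix(runif(15 * 12), 15, 12)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a))
  expect_lt(ssim(a, b), 1)
  expect_gte(ssim(a, b), -1)
})

test_that("ssim matches the naive sliding-window oracle", {
  set.seed(11)
  a <- matrix(runif(13 * 10), 13, 10)
  b <- pmin(pmax(a + rnorm(130, sd = 0.1), 0), 1)
  expect_equal(ssim(a, b), naiveSSIM(a, b), tolerance = 1e-12)
  # negation: structural term goes negative
  expect_equal(ssim(a, 1 - a), naiveSSIM(a, 1 - a), tolerance = 1e-12)
  expect_lt(ssim(a, 1 - a), 0)
  # non-default window size
  expect_equal(ssim(a, b, window = 5), naiveSSIM(a, b, w = 5L),
               tolerance = 1e-12)
})

test_that("ssim on distinct constants matches the closed form", {
  a <- matrix(0.2, 9, 9)
  b <- matrix(0.6, 9, 9)
  Z1 <- 0.01^2; Z2 <- 0.03^2
  want <- ((2 * 0.2 * 0.6 + Z1) * Z2) / ((0.04 + 0.36 + Z1) * Z2)
  expect_equal(ssim(a, b), want)
})

test_that("ssim validates the window", {
  a <- matrix(runif(36), 6, 6)
  expect_error(ssim(a, a, window = 4), "odd")
  expect_error(ssim(a, a, window = 1), "odd")
  expect_error(ssim(a, a, window = 7), "larger than image")
})

test_that("dice and iou match hand-worked examples", {
  i1 <- matrix(c(1, 1, 1, 0), 2, 2)
  i2 <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(diceCoef(i1, i2), 2 * 2 / (3 + 2))  # 0.8
  expect_equal(iou(i1, i2), 2 / 3)
  expect_equal(pixelAccuracy(i1, i2), 0.75)
  # disjoint masks
  expect_equal(diceCoef(diag(2), 1 - diag(2)), 0)
  expect_equal(iou(diag(2), 1 - diag(2)), 0)
})

test_that("empty-vs-empty masks score 1 with a warning", {
  z <- matrix(0, 3, 3)
  expect_warning(d <- diceCoef(z, z), "empty")
  expect_equal(d, 1)
  expect_warning(j <- iou(z, z), "empty")
  expect_equal(j, 1)
  # empty vs non-empty is 0 without warning
  o <- matrix(0, 3, 3); o[1, 1] <- 1
  expect_silent(expect_equal(diceCoef(z, o), 0))
})

test_that("overlap metrics reject non-binary input", {
  expect_error(diceCoef(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
  expect_error(iou(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
  expect_error(pixelAccuracy(matrix(0.3, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("binarize thresholds correctly and validates inputs", {
  p <- matrix(c(0, 0.49, 0.5, 1), 2, 2)
  expect_identical(binarize(p), matrix(c(0, 0, 1, 1), 2, 2))
  expect_identical(binarize(p, 0.95), matrix(c(0, 0, 0, 1), 2, 2))
  expect_error(binarize(p, 0), "strictly inside")
  expect_error(binarize(p, 1), "strictly inside")
  expect_error(binarize(matrix(1.5, 2, 2)), "\\[0, 1\\]")
})
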