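test_that("standardizeRows uses population moments and guards zero variance", {
  st <- standardizeRows(imageStack(list(matrix(2, 1, 1), matrix(4, 1, 1))))
  # row (2, 4): mean 3, population std 1 -> (-1, 1)
  expect_equal(as.numeric(st$X), c(-1, 1))
  expect_equal(as.numeric(st$rowMeans), 3)
  expect_equal(as.numeric(st$rowStds), 1)
  # constant row: centred to zero, std recorded as 1 (no NaN)
  stk <- imageStack(list(matrix(c(0.7, 0.1), 2, 1), matrix(c(0.7, 0.9), 2, 1)))
  st2 <- standardizeRows(stk)
  expect_equal(st2$X[1, ], c(0, 0))
  expect_equal(st2$rowStds[1], 1)
  expect_false(any(is.nan(st2$X)))
})

test_that("fitPCA agrees with the dense covariance eigendecomposition", {
  set.seed(3)
  stk <- imageStack(lapply(1:3, function(i) matrix(runif(4), 2, 2)))
  model <- fitPCA(stk)
  oracle <- denseCovEigen(stk)
  r <- min(nrow(stk@X), ncol(stk@X))
  expect_equal(eigenvalues(model), oracle$values[seq_len(r)], tolerance = 1e-10)
  # eigenvectors match up to sign; compare absolute inner products
  for (j in seq_len(r)) {
    if (eigenvalues(model)[j] < 1e-10) next
    expect_equal(abs(sum(eigenvectors(model)[, j] * oracle$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("fitPCA matches the dense oracle across a dimension sweep", {
  for (seed in 1:12) {
    set.seed(seed)
    D <- sample(2:16, 1)
    N <- sample(2:8, 1)
    X <- matrix(runif(D * N), D, N)
    stk <- new("ImageStack", X = X, width = 1L, height = as.integer(D))
    model <- fitPCA(stk)
    oracle <- denseCovEigen(stk)
    r <- min(D, N)
    expect_equal(eigenvalues(model), oracle$values[seq_len(r)],
                 tolerance = 1e-8)
    # trace identity: retained eigenvalues account for the full variance
    # (rank of the covariance is at most N)
    st <- standardizeRows(stk)
    expect_equal(sum(eigenvalues(model)), sum(st$X^2) / N, tolerance = 1e-8)
    # projection onto the leading eigenvector matches the oracle's
    b1 <- eigenvectors(model)[, 1]
    o1 <- oracle$vectors[, 1]
    expect_equal(b1 %*% t(b1) %*% st$X, o1 %*% t(o1) %*% st$X,
                 tolerance = 1e-8)
  }
})

test_that("eigenvalues are non-increasing and basis orthonormal", {
  set.seed(5)
  stk <- imageStack(lapply(1:6, function(i) matrix(runif(64), 8, 8)))
  model <- fitPCA(stk, K = 4)
  ev <- eigenvalues(model)
  expect_true(all(diff(ev) <= 1e-10))
  B <- model@basis
  expect_equal(crossprod(B), diag(4), tolerance = 1e-10)
})

test_that("full-K reconstruction is lossless; error is monotone in K", {
  set.seed(9)
  imgs <- lapply(1:5, function(i) matrix(runif(36), 6, 6))
  stk <- imageStack(imgs)
  full <- fitPCA(stk)
  rec <- reconstructStack(full, stk)
  expect_equal(rec@X, stk@X, tolerance = 1e-10)
  errs <- vapply(1:5, function(K) {
    m <- fitPCA(stk, K = K)
    mean((reconstructStack(m, stk)@X - stk@X)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[5], 1e-20)
})

test_that("a rank-1 stack yields a single nonzero eigenvalue", {
  set.seed(2)
  base <- matrix(runif(16, 0.2, 0.8), 4, 4)
  stk <- imageStack(list(base * 0.5, base * 1.2, base * 0.8))
  # pure rescalings: every standardised row is identical -> rank 1
  ev <- eigenvalues(fitPCA(stk))
  expect_gt(ev[1], 1e-6)
  expect_lt(max(abs(ev[-1])), 1e-10)
})

test_that("fitPCA validates K and reconstructStack validates dims", {
  stk <- imageStack(list(matrix(runif(4), 2, 2), matrix(runif(4), 2, 2)))
  expect_error(fitPCA(stk, K = 0), "1 <= K")
  expect_error(fitPCA(stk, K = 3), "1 <= K")
  other <- imageStack(list(matrix(runif(9), 3, 3)))
  expect_error(reconstructStack(fitPCA(stk), other), "does not match")
})

test_that("fusing identical images reproduces the image in every mode", {
  set.seed(13)
  img <- matrix(runif(64), 8, 8)
  pair <- imagePair(img, img, id = "same")
  for (mode in c("paper_reconstruct", "eigen_weighted", "average")) {
    expect_equal(pixels(fusePair(pair, mode)), img, tolerance = 1e-10,
                 info = mode)
  }
})

test_that("average fusion of constants is their midpoint and is symmetric", {
  a <- matrix(0.2, 4, 4); b <- matrix(0.6, 4, 4)
  expect_equal(pixels(fusePair(imagePair(a, b, id = "x"), "average")),
               matrix(0.4, 4, 4))
  set.seed(1)
  m <- matrix(runif(16), 4, 4); p <- matrix(runif(16), 4, 4)
  expect_equal(pixels(fusePair(imagePair(m, p, id = "a"), "average")),
               pixels(fusePair(imagePair(p, m, id = "b"), "average")))
})

test_that("eigen-weighted fusion matches the closed-form 2x2 oracle", {
  set.seed(21)
  m <- matrix(runif(100, 0.1, 0.9), 10, 10)
  p <- pmin(pmax(0.7 * m + 0.1 + rnorm(100, sd = 0.05), 0), 1)
  fused <- fusePair(imagePair(m, p, id = "w"), "eigen_weighted")
  # oracle: dominant eigenvector of the population covariance of (m, p)
  M <- cbind(as.numeric(m), as.numeric(p))
  C <- stats::cov(M) * (nrow(M) - 1) / nrow(M)
  v <- eigen(C, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  w <- v / sum(v)
  expect_equal(fused@weights, w, tolerance = 1e-10)
  expect_equal(sum(fused@weights), 1, tolerance = 1e-12)
  expect_equal(pixels(fused), pmin(pmax(w[1] * m + w[2] * p, 0), 1),
               tolerance = 1e-10)
})

test_that("single-image default reconstruction keeps output in unit range", {
  pair <- makePhantomPair(phantomConfig(size = 64, seed = 4), 1)
  fused <- fusePair(pair, "paper_reconstruct")
  expect_true(all(pixels(fused) >= 0 & pixels(fused) <= 1))
  expect_identical(fused@mode, "paper_reconstruct")
  expect_identical(fused@provenance, imageId(pair))
})

test_that("reconstruction against a caller-provided stack uses its basis", {
  set.seed(31)
  imgs <- lapply(1:6, function(i) matrix(runif(64), 8, 8))
  stkM <- imageStack(imgs[1:3])
  stkP <- imageStack(imgs[4:6])
  pair <- imagePair(imgs[[1]], imgs[[4]], id = "s")
  fused <- fusePair(pair, "paper_reconstruct", K = 2,
                    mriStack = stkM, petStack = stkP)
  reconOracle <- function(img, stk) {
    model <- fitPCA(stk, K = 2)
    stackImage(reconstructStack(model, imageStack(img)), 1)
  }
  want <- (reconOracle(imgs[[1]], stkM) + reconOracle(imgs[[4]], stkP)) / 2
  expect_equal(pixels(fused), pmin(pmax(want, 0), 1), tolerance = 1e-12)
  # mismatched stack dims are rejected
  bad <- imageStack(list(matrix(runif(16), 4, 4)))
  expect_error(fusePair(pair, "paper_reconstruct", mriStack = bad),
               "do not match")
})

test_that("scoreFusion reports the four numbers with correct degeneracies", {
  set.seed(17)
  m <- matrix(runif(144), 12, 12)
  p <- matrix(runif(144), 12, 12)
  pair <- imagePair(m, p, id = "sc")
  s <- scoreFusion(m, pair)
  expect_identical(s$psnr_mri, Inf)
  expect_equal(s$ssim_mri, 1)
  expect_lt(s$psnr_pet, Inf)
  sF <- scoreFusion(fusePair(pair, "average"), pair)
  expect_named(sF, c("psnr_mri", "ssim_mri", "psnr_pet", "ssim_pet"))
  expect_true(all(unlist(sF[c(2, 4)]) >= -1 & unlist(sF[c(2, 4)]) <= 1))
})

test_that("PCA fusion scores no worse than plain averaging on phantoms", {
  for (seed in c(2, 8)) {
    pair <- makePhantomPair(phantomConfig(size = 64, seed = seed), 1)
    sP <- scoreFusion(fusePair(pair, "paper_reconstruct"), pair)
    sA <- scoreFusion(fusePair(pair, "average"), pair)
    expect_gte(sP$ssim_mri, sA$ssim_mri - 0.05)
    expect_gte(sP$ssim_pet, sA$ssim_pet - 0.05)
  }
})
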