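# Shared fixtures and independent oracles.

# Naive sliding-window SSIM reference: explicit double loop over windows,
# population moments, standard stabilisers. Independent of the package's
# integral-image implementation.
naiveSSIM <- function(a, b, w = 7L, L = 1) {
  Z1 <- (0.01 * L)^2
  Z2 <- (0.03 * L)^2
  vals <- c()
  for (i in seq_len(nrow(a) - w + 1L)) {
    for (j in seq_len(ncol(a) - w + 1L)) {
      pa <- a[i:(i + w - 1L), j:(j + w - 1L)]
      pb <- b[i:(i + w - 1L), j:(j + w - 1L)]
      ma <- mean(pa); mb <- mean(pb)
      va <- mean((pa - ma)^2); vb <- mean((pb - mb)^2)
      cab <- mean((pa - ma) * (pb - mb))
      vals <- c(vals, ((2 * ma * mb + Z1) * (2 * cab + Z2)) /
                        ((ma^2 + mb^2 + Z1) * (va + vb + Z2)))
    }
  }
  mean(vals)
}

# Small random co-registered pairs (no phantom machinery), for preprocessing
# tests where image content is irrelevant.
randomPairs <- function(n, size = 16L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    msk <- matrix(0, size, size)
    msk[sample(size^2, size)] <- 1
    imagePair(matrix(runif(size^2), size, size),
              matrix(runif(size^2), size, size),
              mask = msk, id = sprintf("rnd_%03d", i))
  })
}

# Dense eigendecomposition oracle for the PCA fusion path: forms the full
# D x D population covariance of the row-standardised stack explicitly.
denseCovEigen <- function(stack) {
  st <- standardizeRows(stack)
  S <- st$X %*% t(st$X) / ncol(st$X)
  eigen(S, symmetric = TRUE)
}

# Frozen per-layer parameter counts of the published full-width layer table,
# in forward order (encoder 5 x [conv, conv, bn], middle [conv, conv, bn],
# decoder 5 x [transpose, conv, conv, bn], head).
TABLE1_PARAMS <- c(
  1792, 36928, 256,
  73856, 147584, 512,
  295168, 590080, 1024,
  1180160, 2359808, 2048,
  4719616, 9438208, 4096,
  18876416, 37750784, 8192,
  8389632, 18875392, 9438208, 4096,
  2097664, 4719104, 1179904, 1024,
  262400, 1179904, 295040, 512,
  65664, 295040, 73792, 256,
  16448, 73792, 36928, 256,
  65)
TABLE1_TRAINABLE_TOTAL <- 122480513
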