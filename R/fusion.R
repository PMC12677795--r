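## Principal-component fusion of co-registered MRI/PET pairs.
##
## The stack of vectorised images is standardised row-wise (per pixel), the
## population covariance S = (1/N) X~ X~^T is eigendecomposed, the first K
## eigenvectors reconstruct each modality, and the reconstructions are
## combined pixel-wise. For D >> N the eigenpairs are computed from the thin
## SVD of X~ (equivalently the N x N Gram matrix), which is mathematically
## identical to the dense D x D eigendecomposition but never forms S.

#' Standardise stack rows
#'
#' Subtracts each row's mean and divides by its population (1/N) standard
#' deviation. Zero-variance rows (constant background pixels are common in
#' brain slices) are mean-centred only, with their std recorded as 1, so no
#' division by zero occurs.
#'
#' @param stack an [ImageStack-class].
#' @return List with `X` (standardised D x N matrix), `rowMeans`, `rowStds`.
#' @examples
#' standardizeRows(imageStack(list(matrix(2, 1, 1), matrix(4, 1, 1))))
#' @export
standardizeRows <- function(stack) {
  X <- stack@X
  if (ncol(X) < 1L) stop("empty stack")
  m <- rowMeans(X)
  Xc <- X - m
  s <- sqrt(rowMeans(Xc^2))
  s[s < 1e-12] <- 1
  list(X = Xc / s, rowMeans = m, rowStds = s)
}

#' Fit a principal-component model to an image stack
#'
#' Eigenpairs of the population covariance `S = (1/N) X~ X~^T` of the
#' row-standardised stack, obtained from the thin SVD of `X~` so the D x D
#' matrix is never formed: singular values `d` give eigenvalues `d^2 / N`
#' and the left singular vectors are the eigenvectors. Eigenvalues are
#' non-increasing; each eigenvector's sign is fixed so its first nonzero
#' component is positive, a stable tie-break when eigenvalues coincide.
#'
#' @param stack an [ImageStack-class].
#' @param K retained component count, `1 <= K <= min(D, N)`; defaults to
#'   `min(D, N)` (complete basis, lossless reconstruction).
#' @return A [PCAModel-class].
#' @export
fitPCA <- function(stack, K = NULL) {
  D <- nrow(stack@X); N <- ncol(stack@X)
  r <- min(D, N)
  if (is.null(K)) K <- r
  K <- as.integer(K)
  if (K < 1L || K > r)
    stop("K must satisfy 1 <= K <= min(D, N) = ", r)
  st <- standardizeRows(stack)
  sv <- svd(st$X, nu = r, nv = 0)
  U <- sv$u
  for (j in seq_len(ncol(U))) {
    nz <- which(abs(U[, j]) > 1e-12)[1]
    if (!is.na(nz) && U[nz, j] < 0) U[, j] <- -U[, j]
  }
  new("PCAModel", rowMeans = st$rowMeans, rowStds = st$rowStds,
      eigenvectors = U, eigenvalues = sv$d[seq_len(r)]^2 / N, K = K,
      basis = U[, seq_len(K), drop = FALSE],
      width = stack@width, height = stack@height)
}

#' Reconstruct a stack from its principal components
#'
#' Standardises the stack with the model's stored row means/stds, projects
#' onto the K-dimensional basis (`X^ = B B^T X~`), then restores the
#' dynamic range by multiplying each row by its standard deviation and
#' adding back its mean. Columns of the result reshape to W x H images via
#' [stackImage()].
#'
#' @param model a [PCAModel-class].
#' @param stack an [ImageStack-class] with the same D as the fitted stack.
#' @return An [ImageStack-class] of reconstructions.
#' @export
reconstructStack <- function(model, stack) {
  if (nrow(stack@X) != length(model@rowMeans))
    stop("stack dimension D does not match the fitted model")
  Xs <- (stack@X - model@rowMeans) / model@rowStds
  B <- model@basis
  Xhat <- B %*% crossprod(B, Xs)
  Xhat <- Xhat * model@rowStds + model@rowMeans
  new("ImageStack", X = Xhat, width = stack@width, height = stack@height)
}

#' Extract one image from a stack
#'
#' @param stack an [ImageStack-class].
#' @param i column index.
#' @return The i-th image as a height x width matrix.
#' @export
stackImage <- function(stack, i = 1L) {
  matrix(stack@X[, i], stack@height, stack@width)
}

## Dominant-eigenvector weights of the 2 x 2 covariance of the two
## modalities, normalised to sum 1; falls back to equal weights when the
## normalisation is degenerate (anti-correlated principal direction).
eigenFusionWeights <- function(a, b) {
  M <- cbind(as.numeric(a), as.numeric(b))
  Mc <- sweep(M, 2, colMeans(M))
  C <- crossprod(Mc) / nrow(M)
  v <- eigen(C, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  if (sum(v) < 1e-12) return(c(0.5, 0.5))
  v / sum(v)
}

#' Fuse a co-registered MRI/PET pair
#'
#' Three pixel-wise fusion rules:
#' \describe{
#'   \item{`paper_reconstruct`}{Each modality's stack is standardised,
#'     decomposed and reconstructed from its first K components
#'     ([fitPCA()] / [reconstructStack()]); the fused image is the
#'     unweighted pixel-wise mean of the two reconstructions. By default
#'     each modality's stack is the single image itself; supplying
#'     `mriStack`/`petStack` fits the components on a larger caller-provided
#'     stack and reconstructs this pair against it.}
#'   \item{`eigen_weighted`}{The classic eigenvector weighting: weights are
#'     the dominant eigenvector of the 2 x 2 covariance of the two images,
#'     normalised to sum 1, and the fused image is `w1 * mri + w2 * pet`.}
#'   \item{`average`}{Plain `(mri + pet) / 2` baseline.}
#' }
#' Output values are clamped to `[0, 1]`.
#'
#' @param pair an [ImagePair-class].
#' @param mode fusion rule.
#' @param K retained components for `paper_reconstruct` (default: all).
#' @param mriStack,petStack optional [ImageStack-class] objects on which the
#'   per-modality components are fitted (must match the pair's dims).
#' @return A [FusedImage-class].
#' @examples
#' p <- makePhantomPair(phantomConfig(size = 64), 1)
#' fusePair(p, "average")
#' @export
fusePair <- function(pair, mode = c("paper_reconstruct", "eigen_weighted",
                                    "average"),
                     K = NULL, mriStack = NULL, petStack = NULL) {
  mode <- match.arg(mode)
  a <- pair@mri; b <- pair@pet
  weights <- numeric(0)
  fused <- switch(mode,
    average = (a + b) / 2,
    eigen_weighted = {
      weights <- eigenFusionWeights(a, b)
      weights[1] * a + weights[2] * b
    },
    paper_reconstruct = {
      reconOne <- function(img, fitStack) {
        own <- imageStack(img)
        if (is.null(fitStack)) fitStack <- own
        if (nrow(fitStack@X) != nrow(own@X))
          stop("supplied stack dims do not match the pair")
        model <- fitPCA(fitStack, K = K)
        stackImage(reconstructStack(model, own), 1L)
      }
      (reconOne(a, mriStack) + reconOne(b, petStack)) / 2
    })
  new("FusedImage", pixels = pmin(pmax(fused, 0), 1), mode = mode,
      provenance = pair@id, weights = weights)
}

#' Score a fused image against its sources
#'
#' PSNR and SSIM of the fused image against each source modality, the four
#' numbers reported per fusion-algorithm comparison.
#'
#' @param fused a [FusedImage-class] or unit-range matrix.
#' @param pair the source [ImagePair-class].
#' @return Named list: `psnr_mri`, `ssim_mri`, `psnr_pet`, `ssim_pet`.
#' @export
scoreFusion <- function(fused, pair) {
  fx <- if (is(fused, "FusedImage")) fused@pixels else fused
  checkSameDims(fx, pair@mri)
  list(psnr_mri = psnr(pair@mri, fx, maxI = 1),
       ssim_mri = ssim(pair@mri, fx, dynamicRange = 1),
       psnr_pet = psnr(pair@pet, fx, maxI = 1),
       ssim_pet = ssim(pair@pet, fx, dynamicRange = 1))
}
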