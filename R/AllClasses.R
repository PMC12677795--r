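setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Raw integer-intensity image
#'
#' A 2-D grayscale image with integer intensities on the scale of its bit
#' depth (8, 12 or 16 bit), the form in which scanner exports and PNG files
#' arrive before intensity normalisation.
#'
#' @slot pixels numeric matrix of intensities in `[0, 2^bitDepth - 1]`.
#' @slot bitDepth integer, one of 8, 12, 16.
#' @export
setClass("RawImage",
  representation(pixels = "matrix", bitDepth = "integer"),
  validity = function(object) {
    bd <- object@bitDepth
    if (length(bd) != 1L || !bd %in% c(8L, 12L, 16L))
      return("bitDepth must be one of 8, 12, 16")
    px <- object@pixels
    if (nrow(px) < 1L || ncol(px) < 1L) return("image must have positive dims")
    if (any(!is.finite(px))) return("pixels must be finite")
    if (min(px) < 0 || max(px) > 2^bd - 1)
      return(sprintf("intensities must lie in [0, %d]", 2^bd - 1L))
    TRUE
  })

#' Construct a RawImage
#'
#' @param pixels numeric matrix of intensities.
#' @param bitDepth integer bit depth (8, 12 or 16).
#' @return A [RawImage-class] object.
#' @examples
#' rawImage(matrix(0:3, 2, 2), bitDepth = 8)
#' @export
rawImage <- function(pixels, bitDepth = 8L) {
  new("RawImage", pixels = as.matrix(pixels), bitDepth = as.integer(bitDepth))
}

#' Co-registered MRI/PET slice pair
#'
#' One co-registered pair of unit-range grayscale slices, optionally with a
#' binary ground-truth tumour mask on the same pixel grid. The `transform`
#' slot records the augmentation transform that produced a derived pair
#' (empty for original pairs), so mask/image co-registration can be audited.
#'
#' @slot mri numeric matrix in `[0, 1]`.
#' @slot pet numeric matrix in `[0, 1]`, same dims as `mri`.
#' @slot mask binary (0/1) matrix with the same dims, or `NULL`.
#' @slot id character identifier.
#' @slot transform list describing the augmentation transform, if any.
#' @export
setClass("ImagePair",
  representation(mri = "matrix", pet = "matrix", mask = "matrixOrNULL",
                 id = "character", transform = "list"),
  prototype(transform = list()),
  validity = function(object) {
    d <- dim(object@mri)
    if (!identical(d, dim(object@pet)))
      return("mri and pet must share dimensions")
    rng <- range(object@mri, object@pet)
    if (any(!is.finite(rng)) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      return("mri and pet intensities must lie in [0, 1]")
    if (!is.null(object@mask)) {
      if (!identical(dim(object@mask), d))
        return("mask must share dimensions with the images")
      if (!all(object@mask %in% c(0, 1)))
        return("mask values must be 0 or 1")
    }
    if (length(object@id) != 1L) return("id must be a single string")
    TRUE
  })

#' Construct an ImagePair
#'
#' @param mri,pet numeric matrices in `[0, 1]` with identical dims.
#' @param mask optional binary matrix with the same dims.
#' @param id character identifier.
#' @param transform optional list recording the transform that produced the
#'   pair (used by [augmentDataset()]).
#' @return An [ImagePair-class] object.
#' @export
imagePair <- function(mri, pet, mask = NULL, id = "pair", transform = list()) {
  new("ImagePair", mri = mri, pet = pet, mask = mask, id = id,
      transform = transform)
}

#' Stack of vectorised images
#'
#' A D-by-N matrix whose columns are vectorised W-by-H images (D = W * H),
#' the input form for the principal-component fusion stage.
#'
#' @slot X numeric matrix, D x N.
#' @slot width,height integer source image dims, with `width * height == D`.
#' @export
setClass("ImageStack",
  representation(X = "matrix", width = "integer", height = "integer"),
  validity = function(object) {
    if (object@width < 1L || object@height < 1L)
      return("width and height must be positive")
    if (nrow(object@X) != object@width * object@height)
      return("nrow(X) must equal width * height")
    if (ncol(object@X) < 1L) return("stack must contain at least one image")
    TRUE
  })

#' Construct an ImageStack from images
#'
#' @param images a single numeric matrix or a list of numeric matrices with
#'   identical dims; each is vectorised column-major into one column of the
#'   stack.
#' @return An [ImageStack-class] object.
#' @examples
#' imageStack(list(matrix(1:4, 2, 2), matrix(5:8, 2, 2)))
#' @export
imageStack <- function(images) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1L)
  d <- dim(images[[1L]])
  if (!all(vapply(images, function(m) identical(dim(m), d), logical(1))))
    stop("all images in a stack must share dimensions")
  X <- vapply(images, as.numeric, numeric(prod(d)))
  if (!is.matrix(X)) X <- matrix(X, ncol = length(images))
  new("ImageStack", X = X, width = as.integer(d[2L]), height = as.integer(d[1L]))
}

#' Principal-component model of an image stack
#'
#' Per-row (per-pixel) means and standard deviations plus the eigenpairs of
#' the population covariance S = (1/N) X~ X~^T of the row-standardised
#' stack, with the first K eigenvectors retained as the projection basis.
#'
#' @slot rowMeans,rowStds numeric length-D vectors.
#' @slot eigenvectors D x min(D, N) matrix with orthonormal columns.
#' @slot eigenvalues non-increasing, non-negative eigenvalues of S.
#' @slot K integer count of retained components.
#' @slot basis D x K matrix, the first K eigenvectors.
#' @slot width,height source image dims.
#' @export
setClass("PCAModel",
  representation(rowMeans = "numeric", rowStds = "numeric",
                 eigenvectors = "matrix", eigenvalues = "numeric",
                 K = "integer", basis = "matrix",
                 width = "integer", height = "integer"),
  validity = function(object) {
    ev <- object@eigenvalues
    if (any(diff(ev) > 1e-8)) return("eigenvalues must be non-increasing")
    if (any(ev < -1e-8)) return("eigenvalues must be non-negative")
    K <- object@K
    if (K < 1L || K > ncol(object@eigenvectors))
      return("K out of range")
    if (ncol(object@basis) != K) return("basis must have K columns")
    G <- crossprod(object@basis)
    if (max(abs(G - diag(K))) > 1e-6)
      return("basis columns must be orthonormal")
    TRUE
  })

#' Fused MRI/PET image
#'
#' @slot pixels numeric matrix in `[0, 1]`.
#' @slot mode fusion rule used: `"paper_reconstruct"`, `"eigen_weighted"` or
#'   `"average"`.
#' @slot provenance id(s) of the source pair.
#' @slot weights modality weights (eigen-weighted mode only; empty otherwise).
#' @export
setClass("FusedImage",
  representation(pixels = "matrix", mode = "character",
                 provenance = "character", weights = "numeric"),
  validity = function(object) {
    rng <- range(object@pixels)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      return("fused pixels must lie in [0, 1]")
    if (!object@mode %in% c("paper_reconstruct", "eigen_weighted", "average"))
      return("unknown fusion mode")
    TRUE
  })

#' Declarative network description
#'
#' Describes the five-level encoder-decoder segmentation network: input
#' geometry, base encoder width (doubled per level), middle width, kernel
#' sizes, and a width multiplier that scales every filter count for
#' desk-scale runs. Input dims must be divisible by 2^5 = 32 (five 2x2
#' stride-2 poolings down to the middle grid); scaled filter counts must be
#' positive integers.
#'
#' @slot inputH,inputW input dims in pixels.
#' @slot inputChannels input channel count (grayscale inputs are replicated).
#' @slot baseFilters first-level encoder filter count before scaling.
#' @slot middleFilters bottleneck filter count before scaling.
#' @slot depth encoder block count (fixed at 5).
#' @slot convKernel,transposeKernel,finalKernel kernel side lengths.
#' @slot widthMultiplier positive rational scaling all filter counts.
#' @export
setClass("NetworkSpec",
  representation(inputH = "integer", inputW = "integer",
                 inputChannels = "integer", baseFilters = "integer",
                 middleFilters = "integer", depth = "integer",
                 convKernel = "integer", transposeKernel = "integer",
                 finalKernel = "integer", widthMultiplier = "numeric"),
  validity = function(object) {
    pool <- 2L^object@depth
    if (object@inputH %% pool != 0L || object@inputW %% pool != 0L)
      return(sprintf(
        "input dims must be divisible by %d: %dx%d pools to %gx%g at the middle grid",
        pool, object@inputH, object@inputW,
        object@inputH / pool, object@inputW / pool))
    if (object@depth != 5L) return("depth is fixed at 5 encoder blocks")
    if (object@widthMultiplier <= 0) return("widthMultiplier must be positive")
    ch <- c(object@baseFilters * 2^(0:4), object@middleFilters) *
      object@widthMultiplier
    if (any(abs(ch - round(ch)) > 1e-9) || any(ch < 1))
      return("scaled filter counts must be positive integers")
    if (object@inputChannels < 1L) return("inputChannels must be >= 1")
    TRUE
  })

#' Segmentation network with weights
#'
#' A built network: its [NetworkSpec-class] plus the named flat list of
#' weight arrays (convolution kernels and biases, transpose-convolution
#' kernels and biases, batch-norm scale/shift and running statistics) in the
#' canonical layer order.
#'
#' @slot spec the [NetworkSpec-class] the weights were built for.
#' @slot weights named list of numeric arrays.
#' @export
setClass("UNetModel",
  representation(spec = "NetworkSpec", weights = "list"))

#' Segmentation result for one pair
#'
#' @slot prob predicted probability map in `[0, 1]`.
#' @slot mask binarised predicted mask.
#' @slot dice,iou,accuracy overlap metrics against ground truth (`NA` when no
#'   truth mask was supplied).
#' @slot id identifier of the segmented pair.
#' @export
setClass("SegmentationResult",
  representation(prob = "matrix", mask = "matrix", dice = "numeric",
                 iou = "numeric", accuracy = "numeric", id = "character"),
  validity = function(object) {
    if (min(object@prob) < -1e-9 || max(object@prob) > 1 + 1e-9)
      return("probability map must lie in [0, 1]")
    if (!all(object@mask %in% c(0, 1))) return("mask must be binary")
    TRUE
  })

#' Phantom generator configuration
#'
#' Parameters of the synthetic co-registered pseudo-MRI/PET phantom
#' generator. The MRI-like channel carries a sharp skull rim, internal
#' texture and a tumour rim; the PET-like channel carries a smooth
#' background plus a high-intensity Gaussian uptake blob centred on the
#' tumour; the mask is the exact tumour ellipse.
#'
#' @slot size image side length in pixels.
#' @slot tumourCountRange integer range (min, max) of tumours per phantom.
#' @slot radiusRange tumour semi-major axis range in pixels.
#' @slot axisRatioRange semi-minor/semi-major axis ratio range.
#' @slot edgeContrast amplitude of the MRI texture and rim contrast.
#' @slot petSigmaFactor Gaussian blob sigma as a multiple of tumour radius.
#' @slot noiseSd additive Gaussian noise sd, `c(mri, pet)`.
#' @slot seed integer base seed; pairs are deterministic in (seed, index).
#' @export
setClass("PhantomConfig",
  representation(size = "integer", tumourCountRange = "integer",
                 radiusRange = "numeric", axisRatioRange = "numeric",
                 edgeContrast = "numeric", petSigmaFactor = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@size < 32L) return("size must be at least 32 pixels")
    if (max(object@radiusRange) >= object@size / 2)
      return("tumour radii must be smaller than half the image size")
    if (any(object@noiseSd < 0)) return("noise sd must be non-negative")
    if (any(object@tumourCountRange < 1L)) return("tumour count must be >= 1")
    if (min(object@axisRatioRange) <= 0 || max(object@axisRatioRange) > 1)
      return("axis ratios must lie in (0, 1]")
    TRUE
  })
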