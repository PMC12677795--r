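#' Accessors for fuseg classes
#'
#' Small accessor generics so slot layout stays an implementation detail:
#' `pixels()` returns the pixel matrix of an image-like object, `mri()`,
#' `pet()` and `tumourMask()` the channels of an [ImagePair-class],
#' `imageId()` its identifier, `eigenvalues()`/`eigenvectors()` the spectrum
#' of a [PCAModel-class], and `probabilityMap()`/`binaryMask()` the outputs
#' of a [SegmentationResult-class].
#'
#' @param object an object of the matching class.
#' @return The matrix or vector held in the corresponding slot.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "RawImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "FusedImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("mri", function(object) standardGeneric("mri"))
#' @rdname accessors
#' @export
setMethod("mri", "ImagePair", function(object) object@mri)

#' @rdname accessors
#' @export
setGeneric("pet", function(object) standardGeneric("pet"))
#' @rdname accessors
#' @export
setMethod("pet", "ImagePair", function(object) object@pet)

#' @rdname accessors
#' @export
setGeneric("tumourMask", function(object) standardGeneric("tumourMask"))
#' @rdname accessors
#' @export
setMethod("tumourMask", "ImagePair", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setMethod("imageId", "ImagePair", function(object) object@id)
#' @rdname accessors
#' @export
setMethod("imageId", "SegmentationResult", function(object) object@id)

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setMethod("eigenvalues", "PCAModel", function(object) object@eigenvalues)

#' @rdname accessors
#' @export
setGeneric("eigenvectors", function(object) standardGeneric("eigenvectors"))
#' @rdname accessors
#' @export
setMethod("eigenvectors", "PCAModel", function(object) object@eigenvectors)

#' @rdname accessors
#' @export
setGeneric("probabilityMap", function(object) standardGeneric("probabilityMap"))
#' @rdname accessors
#' @export
setMethod("probabilityMap", "SegmentationResult", function(object) object@prob)

#' @rdname accessors
#' @export
setGeneric("binaryMask", function(object) standardGeneric("binaryMask"))
#' @rdname accessors
#' @export
setMethod("binaryMask", "SegmentationResult", function(object) object@mask)

setMethod("show", "RawImage", function(object) {
  cat(sprintf("RawImage: %dx%d, %d-bit, range [%g, %g]\n",
              nrow(object@pixels), ncol(object@pixels), object@bitDepth,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ImagePair", function(object) {
  cat(sprintf("ImagePair '%s': %dx%d, mask: %s%s\n", object@id,
              nrow(object@mri), ncol(object@mri),
              if (is.null(object@mask)) "none"
              else sprintf("%d fg px", sum(object@mask)),
              if (length(object@transform)) paste0(
                ", augmented (", object@transform$type, ")") else ""))
})

setMethod("show", "ImageStack", function(object) {
  cat(sprintf("ImageStack: %d images of %dx%d (D = %d)\n", ncol(object@X),
              object@height, object@width, nrow(object@X)))
})

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: D = %d, %d eigenpairs, K = %d retained\n",
              nrow(object@eigenvectors), ncol(object@eigenvectors), object@K))
  cat("  leading eigenvalues:",
      paste(signif(head(object@eigenvalues, 5), 4), collapse = ", "), "\n")
})

setMethod("show", "FusedImage", function(object) {
  cat(sprintf("FusedImage (%s) of %s: %dx%d\n", object@mode,
              paste(object@provenance, collapse = "+"),
              nrow(object@pixels), ncol(object@pixels)))
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf(
    "NetworkSpec: %dx%dx%d input, base %d, middle %d, depth %d, width x%g\n",
    object@inputH, object@inputW, object@inputChannels, object@baseFilters,
    object@middleFilters, object@depth, object@widthMultiplier))
})

setMethod("show", "UNetModel", function(object) {
  cnt <- countModelParameters(object)
  show(object@spec)
  cat(sprintf("  %s parameters (%s trainable)\n",
              format(cnt["total"], big.mark = ","),
              format(cnt["trainable"], big.mark = ",")))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult '%s': %dx%d, %d fg px", object@id,
              nrow(object@mask), ncol(object@mask), sum(object@mask)))
  if (!is.na(object@dice))
    cat(sprintf(", dice %.3f, iou %.3f, acc %.3f",
                object@dice, object@iou, object@accuracy))
  cat("\n")
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %dx%d, %d-%d tumour(s), radius %g-%g px, seed %d\n",
    object@size, object@size, object@tumourCountRange[1],
    object@tumourCountRange[2], object@radiusRange[1], object@radiusRange[2],
    object@seed))
})
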