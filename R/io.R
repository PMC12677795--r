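## Image readers and writers: 8-bit grayscale PNG and NIfTI slices.

#' Read a grayscale PNG as a unit-range matrix
#'
#' Multi-channel PNGs are reduced to their first channel (the expected
#' inputs are single-channel exports).
#'
#' @param path PNG file path.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
readGrayPNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}

#' Read a PNG as a RawImage
#'
#' PNG stores 8- or 16-bit samples; values are mapped back to the integer
#' intensity scale of the file's bit depth so that intensity normalisation
#' can be applied explicitly.
#'
#' @param path PNG file path.
#' @param bitDepth integer bit depth of the stored samples (8 or 16).
#' @return A [RawImage-class].
#' @export
readRawPNG <- function(path, bitDepth = 8L) {
  x <- readGrayPNG(path)
  rawImage(round(x * (2^bitDepth - 1)), bitDepth = as.integer(bitDepth))
}

#' Write a unit-range matrix as an 8-bit grayscale PNG
#'
#' @param img numeric matrix; values are clamped to `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGrayPNG <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read one slice of a NIfTI image
#'
#' Reads `.nii`/`.nii.gz`; for 3-D volumes the requested axial slice is
#' extracted, for 2-D images the slice index is ignored.
#'
#' @param path NIfTI file path.
#' @param slice 1-based slice index along the third axis.
#' @return Numeric matrix of raw intensities.
#' @export
readNiftiSlice <- function(path, slice = 1L) {
  vol <- RNifti::readNifti(path)
  a <- as.array(vol)
  if (length(dim(a)) >= 3L) {
    if (slice < 1L || slice > dim(a)[3L]) stop("slice index out of range")
    a <- a[, , slice]
  }
  as.matrix(a)
}

#' Write a matrix as a 2-D NIfTI image
#'
#' @param img numeric matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeNiftiImage <- function(img, path) {
  RNifti::writeNifti(RNifti::asNifti(img), path)
  invisible(path)
}
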