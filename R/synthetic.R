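## Synthetic co-registered pseudo-MRI/PET phantoms with exact tumour masks.
## The MRI-like channel has sharp structural edges (skull rim, textured
## interior, tumour rim); the PET-like channel is smooth with a
## high-intensity Gaussian uptake blob centred on the tumour. Mask, blob and
## rim share the same ellipse coordinates by construction, so the pairs are
## perfectly co-registered.

#' Construct a phantom generator configuration
#'
#' @param size image side length in pixels (must be >= 32 and should be
#'   divisible by 32 if the phantoms will feed the segmentation network).
#' @param tumourCountRange integer (min, max) tumours per phantom.
#' @param radiusRange tumour semi-major axis range in pixels.
#' @param axisRatioRange semi-minor/semi-major ratio range, in (0, 1].
#' @param edgeContrast amplitude of MRI texture/rim contrast.
#' @param petSigmaFactor blob sigma as a multiple of tumour radius.
#' @param noiseSd additive Gaussian noise sd for (mri, pet).
#' @param seed integer base seed.
#' @return A [PhantomConfig-class] object.
#' @examples
#' phantomConfig(size = 64)
#' @export
phantomConfig <- function(size = 64L, tumourCountRange = c(1L, 1L),
                          radiusRange = c(5, 10), axisRatioRange = c(0.6, 1),
                          edgeContrast = 0.35, petSigmaFactor = 1,
                          noiseSd = c(0.02, 0.02), seed = 1L) {
  if (length(noiseSd) == 1L) noiseSd <- rep(noiseSd, 2L)
  new("PhantomConfig", size = as.integer(size),
      tumourCountRange = as.integer(tumourCountRange),
      radiusRange = as.numeric(radiusRange),
      axisRatioRange = as.numeric(axisRatioRange),
      edgeContrast = edgeContrast, petSigmaFactor = petSigmaFactor,
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

## Squared elliptical distance: <= 1 inside the rotated ellipse.
ellipseField <- function(size, cx, cy, a, b, phi) {
  x <- matrix(seq_len(size), size, size)          # row index
  y <- matrix(seq_len(size), size, size, byrow = TRUE)
  dx <- x - cx; dy <- y - cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  (u / a)^2 + (v / b)^2
}

## Smooth random field: coarse iid grid upsampled bilinearly to size x size.
smoothField <- function(size, coarse = 8L) {
  g <- matrix(runif(coarse^2, -1, 1), coarse, coarse)
  as.matrix(EBImage::resize(g, w = size, h = size, filter = "bilinear"))
}

withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Generate one phantom pair
#'
#' Deterministic in `(seed, index)`: the same configuration and index always
#' yield the same pair, regardless of generation order or the caller's RNG
#' state (which is preserved).
#'
#' @param config a [PhantomConfig-class].
#' @param index positive integer identifying the pair.
#' @return An [ImagePair-class] with a nonempty binary tumour mask.
#' @examples
#' p <- makePhantomPair(phantomConfig(size = 64), 1)
#' sum(tumourMask(p)) > 0
#' @export
makePhantomPair <- function(config, index = 1L) {
  validObject(config)
  index <- as.integer(index)
  if (index < 1L) stop("index must be a positive integer")
  localSeed <- (config@seed %% 97651L) * 21001L + index
  withLocalSeed(localSeed, {
    S <- config@size
    ec <- config@edgeContrast

    ## brain ellipse with jittered centre/axes
    cx <- S / 2 + runif(1, -S / 32, S / 32)
    cy <- S / 2 + runif(1, -S / 32, S / 32)
    ba <- S * runif(1, 0.40, 0.44)
    bb <- S * runif(1, 0.34, 0.40)
    bphi <- runif(1, 0, pi)
    brainE <- ellipseField(S, cx, cy, ba, bb, bphi)
    brain <- brainE <= 1

    ## tumours: centres kept well inside the brain
    nT <- sample(seq(config@tumourCountRange[1], config@tumourCountRange[2]), 1)
    mask <- matrix(0, S, S)
    rimMri <- matrix(0, S, S)
    petBlob <- matrix(0, S, S)
    for (t in seq_len(nT)) {
      r <- runif(1, config@radiusRange[1], config@radiusRange[2])
      q <- runif(1, config@axisRatioRange[1], config@axisRatioRange[2])
      phi <- runif(1, 0, pi)
      rho <- runif(1, 0, 0.5)
      th <- runif(1, 0, 2 * pi)
      tx <- cx + rho * ba * cos(th) * 0.8
      ty <- cy + rho * bb * sin(th) * 0.8
      tE <- ellipseField(S, tx, ty, r, r * q, phi)
      mask[tE <= 1] <- 1
      rimMri[tE > 1 & tE <= 1.55] <- 1
      sig <- config@petSigmaFactor * r
      petBlob <- pmax(petBlob, exp(-tE * (r^2) / (2 * sig^2)))
    }

    ## MRI-like: textured interior, bright skull rim, tumour rim + dark core
    mriTex <- smoothField(S)
    mriImg <- matrix(0.02, S, S)
    mriImg[brain] <- 0.40 + 0.5 * ec * mriTex[brain]
    mriImg[brainE > 1 & brainE <= 1.25] <- 0.90   # skull rim, sharp edge
    mriImg[rimMri == 1 & brain] <- 0.40 + ec      # hyperintense tumour rim
    mriImg[mask == 1] <- 0.40 - 0.6 * ec          # hypointense core

    ## PET-like: smooth background, high-uptake blob on the tumour
    petImg <- matrix(0.03, S, S)
    petBg <- smoothField(S, coarse = 4L)
    petImg[brain] <- 0.18 + 0.05 * petBg[brain]
    petImg <- petImg + 0.75 * petBlob

    mriImg <- mriImg + rnorm(S * S, 0, config@noiseSd[1])
    petImg <- petImg + rnorm(S * S, 0, config@noiseSd[2])
    mriImg <- pmin(pmax(mriImg, 0), 1)
    petImg <- pmin(pmax(petImg, 0), 1)

    imagePair(mriImg, petImg, mask = mask,
              id = sprintf("phantom_%03d", index))
  })
}

#' Generate a phantom dataset
#'
#' @param config a [PhantomConfig-class].
#' @param n number of pairs.
#' @return A list of `n` [ImagePair-class] objects, reproducible from the
#'   config seed.
#' @examples
#' length(makePhantomDataset(phantomConfig(size = 64), 3))
#' @export
makePhantomDataset <- function(config, n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  lapply(seq_len(n), function(i) makePhantomPair(config, i))
}

#' Write an image-pair dataset to disk
#'
#' Writes `mri/`, `pet/` and `mask/` PNG subfolders (masks as 0/255) plus a
#' `manifest.json` listing the pair ids, the layout [readImageDataset()]
#' reads back.
#'
#' @param pairs list of [ImagePair-class] objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeImageDataset <- function(pairs, dir) {
  for (sub in c("mri", "pet", "mask"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(pairs, imageId, character(1))
  for (p in pairs) {
    writeGrayPNG(p@mri, file.path(dir, "mri", paste0(p@id, ".png")))
    writeGrayPNG(p@pet, file.path(dir, "pet", paste0(p@id, ".png")))
    if (!is.null(p@mask))
      writeGrayPNG(p@mask, file.path(dir, "mask", paste0(p@id, ".png")))
  }
  jsonlite::write_json(list(ids = ids, n = length(pairs)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an image-pair dataset from disk
#'
#' Reads the `mri/`, `pet/`, `mask/` PNG layout written by
#' [writeImageDataset()]. PNG quantises intensities to 8 bits, so a write /
#' read round trip preserves images to within 1/255.
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return A list of [ImagePair-class] objects.
#' @export
readImageDataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  lapply(man$ids, function(id) {
    maskPath <- file.path(dir, "mask", paste0(id, ".png"))
    msk <- if (file.exists(maskPath)) {
      m <- readGrayPNG(maskPath)
      (m >= 0.5) + 0
    }
    imagePair(readGrayPNG(file.path(dir, "mri", paste0(id, ".png"))),
              readGrayPNG(file.path(dir, "pet", paste0(id, ".png"))),
              mask = msk, id = id)
  })
}
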