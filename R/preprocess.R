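#' Preprocessing configuration
#'
#' Parameters of the deterministic preprocessing chain applied to every
#' radiograph before feature extraction: depth normalization, margin crop to
#' a fixed physical field of view, directional (compass Sobel) edge
#' enhancement, and box-filter noise reduction.
#'
#' @slot targetBitDepth bit depth after normalization (default 8).
#' @slot cropMM physical crop size, width then height, in mm
#'   (default 180 x 100).
#' @slot sobelAnglesDeg compass kernel orientations in degrees; multiples of
#'   45 covering the 8 directions.
#' @slot edgeGain multiplicative gain applied to the signed Sobel responses
#'   (default 1.8).
#' @slot edgeGainMode how \code{edgeGain} is applied; only
#'   \code{"multiplicative"} is implemented.
#' @slot meanFilterSize side length of the averaging filter (default 6; even
#'   sizes anchor at the top-left pixel of the center 2x2 block).
#' @slot fallbackCropFraction fraction of columns/rows removed from each
#'   side when pixel spacing is unknown (default 0.05, 0.05).
#' @export
setClass("PreprocessConfig",
  representation(
    targetBitDepth = "integer",
    cropMM = "numeric",
    sobelAnglesDeg = "numeric",
    edgeGain = "numeric",
    edgeGainMode = "character",
    meanFilterSize = "integer",
    fallbackCropFraction = "numeric"
  ),
  prototype(
    targetBitDepth = 8L,
    cropMM = c(180, 100),
    sobelAnglesDeg = seq(0, 315, by = 45),
    edgeGain = 1.8,
    edgeGainMode = "multiplicative",
    meanFilterSize = 6L,
    fallbackCropFraction = c(0.05, 0.05)
  )
)

setValidity("PreprocessConfig", function(object) {
  msgs <- character(0)
  if (object@edgeGain <= 0) msgs <- c(msgs, "edgeGain must be > 0")
  if (object@meanFilterSize < 1) msgs <- c(msgs, "meanFilterSize must be >= 1")
  if (length(object@cropMM) != 2 || any(object@cropMM <= 0))
    msgs <- c(msgs, "cropMM must be two positive values (width, height)")
  a <- object@sobelAnglesDeg
  if (any(a %% 45 != 0) || length(unique(a %% 360)) != 8)
    msgs <- c(msgs, "sobelAnglesDeg must be 8 distinct multiples of 45")
  if (object@edgeGainMode != "multiplicative")
    msgs <- c(msgs, "only multiplicative edgeGainMode is implemented")
  f <- object@fallbackCropFraction
  if (length(f) != 2 || any(f < 0) || any(f >= 0.5))
    msgs <- c(msgs, "fallbackCropFraction must be two fractions in [0, 0.5)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname PreprocessConfig-class
#' @param targetBitDepth,cropMM,sobelAnglesDeg,edgeGain,edgeGainMode
#'   see the corresponding slots.
#' @param meanFilterSize,fallbackCropFraction see the corresponding slots.
#' @return A \code{PreprocessConfig}.
#' @examples
#' cfg <- PreprocessConfig(edgeGain = 2)
#' @export
PreprocessConfig <- function(targetBitDepth = 8L, cropMM = c(180, 100),
                             sobelAnglesDeg = seq(0, 315, by = 45),
                             edgeGain = 1.8,
                             edgeGainMode = "multiplicative",
                             meanFilterSize = 6L,
                             fallbackCropFraction = c(0.05, 0.05)) {
  new("PreprocessConfig", targetBitDepth = as.integer(targetBitDepth),
      cropMM = as.numeric(cropMM), sobelAnglesDeg = as.numeric(sobelAnglesDeg),
      edgeGain = edgeGain, edgeGainMode = edgeGainMode,
      meanFilterSize = as.integer(meanFilterSize),
      fallbackCropFraction = as.numeric(fallbackCropFraction))
}

# half-away-from-zero rounding: platform-stable pixel quantization
.roundHalfUp <- function(x) floor(x + 0.5)

#' Compass Sobel kernel for a given orientation
#'
#' The 0-degree kernel is the standard horizontal-gradient Sobel operator
#' \code{[[-1,0,1],[-2,0,2],[-1,0,1]]}; each further 45-degree step rotates
#' the 8 border coefficients one position clockwise about the center, giving
#' the classical compass-operator family (closed under 90-degree rotation).
#'
#' @param angleDeg orientation in degrees; must be a multiple of 45.
#' @return A 3x3 numeric kernel (applied as correlation).
#' @examples
#' compassSobelKernel(0)
#' compassSobelKernel(45)
#' @export
compassSobelKernel <- function(angleDeg) {
  if (angleDeg %% 45 != 0) stop("angle must be a multiple of 45 degrees")
  steps <- (angleDeg / 45) %% 8
  base <- c(-1, 0, 1, 2, 1, 0, -1, -2)  # clockwise from top-left
  rot <- base[((seq(0, 7) - steps) %% 8) + 1]
  k <- matrix(0, 3, 3)
  pos <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3),
               c(3, 3), c(3, 2), c(3, 1), c(2, 1))
  k[pos] <- rot
  k
}

#' Normalize the color depth of a radiograph
#'
#' Linearly rescales the full declared intensity range: value \code{v}
#' maps to \code{round(v * (2^t - 1) / (2^b - 1))} for source depth \code{b}
#' and target depth \code{t}. Rescaling is by declared depth, not per-image
#' min-max, so it is deterministic and insensitive to outlier pixels.
#'
#' @param rg a [Radiograph-class].
#' @param targetBitDepth target depth; must not exceed the source depth.
#' @return The depth-normalized [Radiograph-class]; metadata preserved.
#' @examples
#' rg <- Radiograph(matrix(4095, 5, 5), bitDepth = 12)
#' max(pixelData(normalizeDepth(rg, 8)))  # 255
#' @export
normalizeDepth <- function(rg, targetBitDepth = 8L) {
  stopifnot(is(rg, "Radiograph"))
  t <- as.integer(targetBitDepth)
  b <- rg@bitDepth
  if (t > b)
    stop("target bit depth (", t, ") exceeds source bit depth (", b, ")")
  px <- if (t == b) rg@pixels
        else .roundHalfUp(rg@pixels * (2^t - 1) / (2^b - 1))
  .withPixels(rg, px, bitDepth = t, stage = "normalize_depth",
              params = list(target_bit_depth = t))
}

#' Crop radiograph margins to a fixed physical field of view
#'
#' With known pixel spacing, a centered crop of \code{cropMM / spacingMM}
#' pixels (rounded) per axis is taken; requesting a physical extent larger
#' than the image is an error. Without spacing metadata, a symmetric
#' fractional crop (\code{fallbackCropFraction} per side) is applied.
#'
#' @param rg a [Radiograph-class].
#' @param cfg a [PreprocessConfig-class].
#' @return The cropped [Radiograph-class].
#' @export
cropMargins <- function(rg, cfg = PreprocessConfig()) {
  stopifnot(is(rg, "Radiograph"), is(cfg, "PreprocessConfig"))
  nr <- nrow(rg@pixels); nc <- ncol(rg@pixels)
  sp <- rg@spacingMM
  if (length(sp) == 2L) {
    extent <- c(nc * sp[1], nr * sp[2])
    if (extent[1] < cfg@cropMM[1] || extent[2] < cfg@cropMM[2])
      stop(sprintf(
        "physical extent %.1f x %.1f mm is smaller than the %g x %g mm crop",
        extent[1], extent[2], cfg@cropMM[1], cfg@cropMM[2]))
    wpx <- min(nc, .roundHalfUp(cfg@cropMM[1] / sp[1]))
    hpx <- min(nr, .roundHalfUp(cfg@cropMM[2] / sp[2]))
  } else {
    wpx <- nc - 2L * floor(nc * cfg@fallbackCropFraction[1])
    hpx <- nr - 2L * floor(nr * cfg@fallbackCropFraction[2])
  }
  c0 <- floor((nc - wpx) / 2)
  r0 <- floor((nr - hpx) / 2)
  px <- rg@pixels[(r0 + 1):(r0 + hpx), (c0 + 1):(c0 + wpx), drop = FALSE]
  .withPixels(rg, px, stage = "crop_margins",
              params = list(crop_mm = cfg@cropMM,
                            rows = hpx, cols = wpx))
}

#' Directional edge enhancement with the compass Sobel bank
#'
#' Correlates the image with the 8 compass Sobel kernels, multiplies each
#' signed response by \code{edgeGain}, takes the pixel-wise maximum over all
#' orientations, and clips to \code{[0, 255]}. Replicate padding is used at
#' the borders. A constant image therefore maps to zero everywhere, and the
#' output is invariant to adding a constant offset to the input.
#'
#' @param rg an 8-bit [Radiograph-class].
#' @param cfg a [PreprocessConfig-class].
#' @return The edge-enhanced 8-bit [Radiograph-class].
#' @export
enhanceEdges <- function(rg, cfg = PreprocessConfig()) {
  stopifnot(is(rg, "Radiograph"), is(cfg, "PreprocessConfig"))
  if (rg@bitDepth != 8L)
    stop("edge enhancement requires an 8-bit input (got ",
         rg@bitDepth, "-bit)")
  resp <- NULL
  for (a in cfg@sobelAnglesDeg) {
    r <- .correlate2_replicate(rg@pixels, compassSobelKernel(a)) * cfg@edgeGain
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  px <- .roundHalfUp(pmin(pmax(resp, 0), 255))
  .withPixels(rg, px, stage = "edge_enhance",
              params = list(edge_gain = cfg@edgeGain,
                            angles_deg = cfg@sobelAnglesDeg))
}

#' Averaging-filter noise reduction
#'
#' Box mean of side \code{meanFilterSize} with replicate borders; even sizes
#' anchor the window at the top-left pixel of its center 2x2 block. Values
#' are rounded to the nearest integer.
#'
#' @param rg a [Radiograph-class].
#' @param cfg a [PreprocessConfig-class].
#' @return The smoothed [Radiograph-class].
#' @export
smoothImage <- function(rg, cfg = PreprocessConfig()) {
  stopifnot(is(rg, "Radiograph"), is(cfg, "PreprocessConfig"))
  px <- .roundHalfUp(.box_mean_replicate(rg@pixels, cfg@meanFilterSize))
  .withPixels(rg, px, stage = "smooth",
              params = list(mean_filter_size = cfg@meanFilterSize))
}

#' Full preprocessing chain
#'
#' Applies, in order: depth normalization, margin crop, directional edge
#' enhancement, and averaging-filter smoothing. The chain is deterministic
#' and side-effect free; repeated calls yield bit-identical pixel grids.
#' Every stage records its parameters in the [processingLog()].
#'
#' @param rg a [Radiograph-class].
#' @param cfg a [PreprocessConfig-class].
#' @return The preprocessed 8-bit [Radiograph-class].
#' @examples
#' rg <- Radiograph(matrix(1000, 50, 80), bitDepth = 12)
#' out <- preprocessRadiograph(rg)
#' max(pixelData(out))  # 0: constant images have no edges
#' @export
preprocessRadiograph <- function(rg, cfg = PreprocessConfig()) {
  out <- normalizeDepth(rg, cfg@targetBitDepth)
  out <- cropMargins(out, cfg)
  out <- enhanceEdges(out, cfg)
  smoothImage(out, cfg)
}
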