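#' Feature-extraction configuration
#'
#' Parameters of the KAZE-family keypoint extractor: a nonlinear-diffusion
#' scale space organized in octaves (each octave decimates the grid by two)
#' with a fixed number of sublevels per octave, scale-normalized
#' determinant-of-Hessian detection, and upright (rotation-variant)
#' real-valued 64-dimensional descriptors. Radiographs have a canonical
#' orientation, so the upright descriptor is the appropriate variant.
#'
#' @slot octaves number of octaves (default 8; internally capped when the
#'   image becomes too small to decimate further).
#' @slot layersPerOctave sublevels per octave (default 5).
#' @slot diffusivity conductivity function of the nonlinear diffusion:
#'   one of \code{"PM_G1"}, \code{"PM_G2"}, \code{"WEICKERT"},
#'   \code{"CHARBONNIER"} (default \code{"PM_G2"}).
#' @slot upright logical; only \code{TRUE} (upright descriptors) is
#'   implemented.
#' @slot detectorThreshold minimum scale-normalized determinant-of-Hessian
#'   response for a keypoint (default 1e-4 on images scaled to [0, 1]).
#' @slot maxKeypoints keep at most this many strongest keypoints
#'   (default 300; 0 means unlimited).
#' @export
setClass("FeatureConfig",
  representation(
    octaves = "integer",
    layersPerOctave = "integer",
    diffusivity = "character",
    upright = "logical",
    detectorThreshold = "numeric",
    maxKeypoints = "integer"
  ),
  prototype(
    octaves = 8L,
    layersPerOctave = 5L,
    diffusivity = "PM_G2",
    upright = TRUE,
    detectorThreshold = 1e-4,
    maxKeypoints = 300L
  )
)

.DIFFUSIVITIES <- c(PM_G1 = 1L, PM_G2 = 2L, WEICKERT = 3L, CHARBONNIER = 4L)

setValidity("FeatureConfig", function(object) {
  msgs <- character(0)
  if (object@octaves < 1) msgs <- c(msgs, "octaves must be >= 1")
  if (object@layersPerOctave < 1)
    msgs <- c(msgs, "layersPerOctave must be >= 1")
  if (!object@diffusivity %in% names(.DIFFUSIVITIES))
    msgs <- c(msgs, "unknown diffusivity")
  if (!isTRUE(object@upright))
    msgs <- c(msgs, "only upright descriptors are implemented")
  if (object@detectorThreshold <= 0)
    msgs <- c(msgs, "detectorThreshold must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @rdname FeatureConfig-class
#' @param octaves,layersPerOctave,diffusivity,upright see slots.
#' @param detectorThreshold,maxKeypoints see slots.
#' @return A \code{FeatureConfig}.
#' @export
FeatureConfig <- function(octaves = 8L, layersPerOctave = 5L,
                          diffusivity = "PM_G2", upright = TRUE,
                          detectorThreshold = 1e-4, maxKeypoints = 300L) {
  new("FeatureConfig", octaves = as.integer(octaves),
      layersPerOctave = as.integer(layersPerOctave),
      diffusivity = diffusivity, upright = upright,
      detectorThreshold = detectorThreshold,
      maxKeypoints = as.integer(maxKeypoints))
}

#' KeypointSet: keypoints with descriptors
#'
#' Detected keypoints (position in pixels, scale, detector response) and
#' their fixed-length real descriptor vectors, together with the shape of
#' the image they were extracted from. The descriptors are stored at 32-bit
#' float precision (quantized once at extraction), so serialization round
#' trips are bit-exact.
#'
#' @slot keypoints data.frame with columns \code{x}, \code{y}, \code{scale},
#'   \code{response} (0-based pixel coordinates).
#' @slot descriptors numeric matrix, one row per keypoint.
#' @slot imageShape integer(2): rows, cols of the source image.
#' @export
setClass("KeypointSet",
  representation(
    keypoints = "data.frame",
    descriptors = "matrix",
    imageShape = "integer"
  )
)

setValidity("KeypointSet", function(object) {
  msgs <- character(0)
  kp <- object@keypoints
  if (!all(c("x", "y", "scale", "response") %in% names(kp)))
    msgs <- c(msgs, "keypoints must have columns x, y, scale, response")
  if (nrow(kp) != nrow(object@descriptors))
    msgs <- c(msgs, "keypoint and descriptor counts must match")
  if (length(object@imageShape) != 2)
    msgs <- c(msgs, "imageShape must be (rows, cols)")
  else if (nrow(kp) > 0) {
    if (any(kp$x < 0) || any(kp$x > object@imageShape[2] - 1) ||
        any(kp$y < 0) || any(kp$y > object@imageShape[1] - 1))
      msgs <- c(msgs, "keypoint coordinates must lie inside imageShape")
  }
  if (length(msgs)) msgs else TRUE
})

# quantize a numeric matrix through 32-bit floats (little-endian)
.f32 <- function(m) {
  v <- readBin(writeBin(as.vector(m), raw(), size = 4L, endian = "little"),
               "double", n = length(m), size = 4L, endian = "little")
  matrix(v, nrow = nrow(m), ncol = ncol(m))
}

#' @rdname KeypointSet-class
#' @param keypoints,descriptors,imageShape see slots.
#' @export
KeypointSet <- function(keypoints, descriptors, imageShape) {
  if (is.null(dim(descriptors)))
    descriptors <- matrix(descriptors, nrow = nrow(keypoints))
  new("KeypointSet", keypoints = as.data.frame(keypoints),
      descriptors = descriptors, imageShape = as.integer(imageShape))
}

#' @describeIn KeypointSet number of keypoints.
#' @param x a \code{KeypointSet}.
#' @export
setMethod("nKeypoints", "KeypointSet", function(x) nrow(x@keypoints))

#' @describeIn KeypointSet descriptor vector length (0 when empty).
#' @export
setMethod("descriptorLength", "KeypointSet",
          function(x) ncol(x@descriptors))

#' @describeIn KeypointSet keypoint table.
#' @export
setMethod("keypoints", "KeypointSet", function(x) x@keypoints)

#' @describeIn KeypointSet descriptor matrix.
#' @export
setMethod("descriptors", "KeypointSet", function(x) x@descriptors)

#' @describeIn KeypointSet source image shape (rows, cols).
#' @export
setMethod("imageShape", "KeypointSet", function(x) x@imageShape)

setMethod("show", "KeypointSet", function(object) {
  cat(sprintf("KeypointSet: %d keypoints (descriptor length %d) from %d x %d image\n",
              nKeypoints(object), descriptorLength(object),
              object@imageShape[1], object@imageShape[2]))
})

#' Extract keypoints and descriptors from a preprocessed radiograph
#'
#' Builds a Perona-Malik nonlinear-diffusion scale space over the requested
#' octaves/sublevels, detects scale-normalized determinant-of-Hessian maxima
#' (3x3x3 non-maximum suppression), and computes upright real-valued 64-d
#' descriptors (4x4 subregions of Gaussian-weighted first-derivative sums).
#' Deterministic: identical inputs give identical serialized features.
#'
#' @param rg an 8-bit, preprocessed [Radiograph-class].
#' @param cfg a [FeatureConfig-class].
#' @return A [KeypointSet-class]; empty (with a warning) when the image has
#'   no detectable structure.
#' @export
extractFeatures <- function(rg, cfg = FeatureConfig()) {
  stopifnot(is(rg, "Radiograph"), is(cfg, "FeatureConfig"))
  if (rg@bitDepth != 8L)
    stop("feature extraction requires an 8-bit input")
  res <- .kaze_extract(rg@pixels, cfg@octaves, cfg@layersPerOctave,
                       .DIFFUSIVITIES[[cfg@diffusivity]],
                       cfg@detectorThreshold, cfg@maxKeypoints)
  kp <- as.data.frame(res$keypoints)
  desc <- res$descriptors
  if (nrow(kp) == 0) {
    warning("no keypoints detected; returning an empty KeypointSet")
    desc <- matrix(numeric(0), nrow = 0, ncol = 64)
  } else {
    desc <- .f32(desc)
  }
  KeypointSet(kp, desc, dim(rg@pixels))
}

.KPS_MAGIC <- charToRaw("OKPS")
.KPS_VERSION <- 1L

#' Serialize a KeypointSet to a compact binary blob
#'
#' Layout: 4-byte magic, int32 version, int32 rows/cols/n/descriptor length,
#' then per-keypoint records (x, y, scale, response as float64) and the
#' descriptor matrix row-major as little-endian 32-bit floats.
#'
#' @param ks a [KeypointSet-class].
#' @return A raw vector.
#' @seealso [deserializeKeypointSet()], [keypointSetToJSON()]
#' @export
serializeKeypointSet <- function(ks) {
  stopifnot(is(ks, "KeypointSet"))
  n <- nKeypoints(ks)
  dlen <- descriptorLength(ks)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(.KPS_MAGIC, con)
  writeBin(c(.KPS_VERSION, ks@imageShape[1], ks@imageShape[2],
             n, dlen), con, size = 4L, endian = "little")
  if (n > 0) {
    kp <- ks@keypoints
    rec <- as.vector(t(cbind(kp$x, kp$y, kp$scale, kp$response)))
    writeBin(rec, con, size = 8L, endian = "little")
    writeBin(as.vector(t(ks@descriptors)), con, size = 4L,
             endian = "little")
  }
  rawConnectionValue(con)
}

#' @rdname serializeKeypointSet
#' @param blob raw vector produced by \code{serializeKeypointSet}.
#' @export
deserializeKeypointSet <- function(blob) {
  con <- rawConnection(blob, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic, .KPS_MAGIC))
    stop("corrupt feature blob: bad magic bytes")
  hdr <- readBin(con, "integer", n = 5L, size = 4L, endian = "little")
  if (hdr[1] != .KPS_VERSION)
    stop("unsupported feature blob version: ", hdr[1])
  n <- hdr[4]; dlen <- hdr[5]
  if (n > 0) {
    rec <- readBin(con, "double", n = 4L * n, size = 8L, endian = "little")
    if (length(rec) != 4L * n) stop("corrupt feature blob: truncated records")
    m <- matrix(rec, ncol = 4L, byrow = TRUE)
    kp <- data.frame(x = m[, 1], y = m[, 2], scale = m[, 3],
                     response = m[, 4])
    dv <- readBin(con, "double", n = n * dlen, size = 4L, endian = "little")
    if (length(dv) != n * dlen)
      stop("corrupt feature blob: truncated descriptors")
    desc <- matrix(dv, nrow = n, ncol = dlen, byrow = TRUE)
  } else {
    kp <- data.frame(x = numeric(0), y = numeric(0), scale = numeric(0),
                     response = numeric(0))
    desc <- matrix(numeric(0), nrow = 0, ncol = dlen)
  }
  KeypointSet(kp, desc, hdr[2:3])
}

#' JSON debug dump of a KeypointSet
#'
#' @param ks a [KeypointSet-class].
#' @param path optional file to write to.
#' @return JSON string (invisibly when \code{path} is given).
#' @export
keypointSetToJSON <- function(ks, path = NULL) {
  stopifnot(is(ks, "KeypointSet"))
  obj <- list(version = .KPS_VERSION,
              image_shape = ks@imageShape,
              keypoints = ks@keypoints,
              descriptors = ks@descriptors)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
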