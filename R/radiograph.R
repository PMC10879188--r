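#' Radiograph: a grayscale radiographic image with acquisition metadata
#'
#' Container for a single panoramic radiograph (orthopantomogram, OPG): an
#' integer-valued intensity grid together with its declared bit depth,
#' optional physical pixel spacing, and optional identity / chronological-age
#' labels. Pixel values are stored as a numeric matrix but are always whole
#' numbers in \code{[0, 2^bitDepth - 1]}.
#'
#' @slot pixels numeric matrix of whole-number intensities (rows x cols).
#' @slot bitDepth integer in \code{[8, 16]}; all pixels are < \code{2^bitDepth}.
#' @slot spacingMM numeric of length 0 (unknown) or 2: mm per pixel,
#'   horizontal (x) then vertical (y).
#' @slot individualId opaque identifier of the imaged individual (or NA).
#' @slot ageYears chronological age in years at acquisition (or NA).
#' @slot processingLog list of stage records appended by preprocessing
#'   operations; each record has elements \code{stage} and \code{params}.
#'
#' @seealso [preprocessRadiograph()], [readRadiograph()]
#' @export
setClass("Radiograph",
  representation(
    pixels = "matrix",
    bitDepth = "integer",
    spacingMM = "numeric",
    individualId = "character",
    ageYears = "numeric",
    processingLog = "list"
  ),
  prototype(
    bitDepth = 8L,
    spacingMM = numeric(0),
    individualId = NA_character_,
    ageYears = NA_real_,
    processingLog = list()
  )
)

setValidity("Radiograph", function(object) {
  p <- object@pixels
  msgs <- character(0)
  if (!is.numeric(p)) msgs <- c(msgs, "pixels must be a numeric matrix")
  if (nrow(p) < 3 || ncol(p) < 3)
    msgs <- c(msgs, "pixel grid must have at least 3 rows and 3 columns")
  bd <- object@bitDepth
  if (length(bd) != 1 || is.na(bd) || bd < 8 || bd > 16)
    msgs <- c(msgs, "bitDepth must be a single integer in [8, 16]")
  else {
    if (any(p < 0) || any(p >= 2^bd))
      msgs <- c(msgs, sprintf("pixel values must lie in [0, 2^%d - 1]", bd))
    if (any(p != floor(p)))
      msgs <- c(msgs, "pixel values must be whole numbers")
  }
  sp <- object@spacingMM
  if (!(length(sp) %in% c(0L, 2L)))
    msgs <- c(msgs, "spacingMM must have length 0 or 2")
  if (length(sp) == 2L && (any(is.na(sp)) || any(sp <= 0)))
    msgs <- c(msgs, "spacingMM values must be positive")
  if (!is.na(object@ageYears) && object@ageYears < 0)
    msgs <- c(msgs, "ageYears must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Radiograph
#'
#' @param pixels numeric matrix of whole-number intensities.
#' @param bitDepth declared color depth in bits (8-16).
#' @param spacingMM optional numeric(2): mm per pixel, x then y. A single
#'   value is recycled to both axes.
#' @param individualId optional individual identifier.
#' @param ageYears optional chronological age in years.
#' @return A [Radiograph-class] object.
#' @examples
#' rg <- Radiograph(matrix(0, 10, 20), bitDepth = 8)
#' dim(pixelData(rg))
#' @export
Radiograph <- function(pixels, bitDepth = 8L, spacingMM = NULL,
                       individualId = NA_character_, ageYears = NA_real_) {
  storage.mode(pixels) <- "double"
  if (is.null(spacingMM)) spacingMM <- numeric(0)
  if (length(spacingMM) == 1L) spacingMM <- rep(spacingMM, 2L)
  new("Radiograph", pixels = pixels, bitDepth = as.integer(bitDepth),
      spacingMM = as.numeric(spacingMM),
      individualId = as.character(individualId),
      ageYears = as.numeric(ageYears))
}

#' @describeIn Radiograph pixel intensity matrix.
#' @param x a \code{Radiograph}.
#' @export
setMethod("pixelData", "Radiograph", function(x) x@pixels)

#' @describeIn Radiograph declared bit depth.
#' @export
setMethod("bitDepth", "Radiograph", function(x) x@bitDepth)

#' @describeIn Radiograph pixel spacing in mm (length 0 if unknown).
#' @export
setMethod("spacingMM", "Radiograph", function(x) x@spacingMM)

#' @describeIn Radiograph individual identifier.
#' @export
setMethod("individualId", "Radiograph", function(x) x@individualId)

#' @describeIn Radiograph age in years at acquisition.
#' @export
setMethod("ageYears", "Radiograph", function(x) x@ageYears)

#' @describeIn Radiograph list of preprocessing stage records.
#' @export
setMethod("processingLog", "Radiograph", function(x) x@processingLog)

setMethod("show", "Radiograph", function(object) {
  sp <- if (length(object@spacingMM))
    sprintf("%.3g x %.3g mm/px", object@spacingMM[1], object@spacingMM[2])
  else "unknown spacing"
  cat(sprintf("Radiograph: %d x %d px, %d-bit, %s\n",
              nrow(object@pixels), ncol(object@pixels),
              object@bitDepth, sp))
  if (!is.na(object@individualId))
    cat(sprintf("  individual: %s", object@individualId),
        if (!is.na(object@ageYears))
          sprintf(" (age %.1f years)", object@ageYears) else "", "\n",
        sep = "")
  if (length(object@processingLog))
    cat(sprintf("  processing stages: %s\n",
                paste(vapply(object@processingLog, `[[`, "", "stage"),
                      collapse = " -> ")))
})

# internal: replace the pixel grid, keep metadata, append a log record
.withPixels <- function(rg, pixels, bitDepth = rg@bitDepth,
                        spacingMM = rg@spacingMM, stage = NULL,
                        params = list()) {
  log <- rg@processingLog
  if (!is.null(stage)) log <- c(log, list(list(stage = stage, params = params)))
  new("Radiograph", pixels = pixels, bitDepth = as.integer(bitDepth),
      spacingMM = spacingMM, individualId = rg@individualId,
      ageYears = rg@ageYears, processingLog = log)
}

#' Read a grayscale radiograph from PNG or TIFF
#'
#' 8-bit files yield intensities in \code{[0, 255]}; 16-bit files in
#' \code{[0, 65535]}. Multi-channel images are rejected.
#'
#' @param path file path; format inferred from the extension
#'   (\code{.png}, \code{.tif}, \code{.tiff}).
#' @param bitDepth declared bit depth; defaults to the container depth
#'   (8 or 16) inferred from the file.
#' @param spacingMM,individualId,ageYears metadata, as in [Radiograph()].
#' @return A [Radiograph-class].
#' @export
readRadiograph <- function(path, bitDepth = NULL, spacingMM = NULL,
                           individualId = NA_character_,
                           ageYears = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    depth <- attr(img, "bit.depth")
    if (is.null(depth)) depth <- 8L
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = FALSE)
    depth <- attr(img, "bits.per.sample")
    if (is.null(depth)) depth <- if (max(img) > 1) 16L else 8L
    if (depth > 8) depth <- 16L else depth <- 8L
  } else stop("unsupported image format: .", ext)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1 &&
        !all(abs(img[, , 1] - img[, , min(2, dim(img)[3])]) < 1e-9))
      stop("multi-channel images are not supported")
    img <- img[, , 1]
  }
  maxv <- 2^depth - 1
  px <- floor(img * maxv + 0.5)
  if (is.null(bitDepth)) bitDepth <- depth
  Radiograph(px, bitDepth = bitDepth, spacingMM = spacingMM,
             individualId = individualId, ageYears = ageYears)
}

#' Write a radiograph to PNG or TIFF
#'
#' @param rg a [Radiograph-class].
#' @param path output path; format inferred from the extension.
#' @return \code{path}, invisibly.
#' @export
writeRadiograph <- function(rg, path) {
  stopifnot(is(rg, "Radiograph"))
  ext <- tolower(tools::file_ext(path))
  maxv <- 2^rg@bitDepth - 1
  img <- rg@pixels / maxv
  if (ext == "png") {
    png::writePNG(img, path, dpi = NULL)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path,
                    bits.per.sample = if (rg@bitDepth > 8) 16L else 8L)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Read or write a sidecar image manifest
#'
#' The manifest is a plain CSV/TSV table with columns \code{path},
#' \code{individual_id}, \code{age_years}, \code{spacing_mm_x},
#' \code{spacing_mm_y} that carries the metadata not stored in the image
#' containers themselves.
#'
#' @param path manifest file; tab-separated if the extension is
#'   \code{.tsv}, comma-separated otherwise.
#' @return \code{readImageManifest}: a data.frame with the columns above.
#' @export
readImageManifest <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("path", "individual_id", "age_years")
  if (!all(need %in% names(df)))
    stop("manifest must contain columns: ", paste(need, collapse = ", "))
  if (!"spacing_mm_x" %in% names(df)) df$spacing_mm_x <- NA_real_
  if (!"spacing_mm_y" %in% names(df)) df$spacing_mm_y <- NA_real_
  df
}

#' @rdname readImageManifest
#' @param manifest data.frame in the manifest layout.
#' @export
writeImageManifest <- function(manifest, path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  utils::write.table(manifest, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
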