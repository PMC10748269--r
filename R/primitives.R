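#' Linear range normalization with clipping
#'
#' Rescales \code{x} linearly so that \code{lo} maps to 0 and \code{hi} maps
#' to 1, then clips to \code{[0, 1]}. This is the \code{norm(x, min, max)}
#' operator used throughout the feature descriptors; it is order-preserving on
#' \code{[lo, hi]} and idempotent for \code{lo = 0, hi = 1} on already-clipped
#' input. Clipping before or after the linear map is equivalent.
#'
#' @param x numeric vector, matrix or array.
#' @param lo,hi real normalization bounds, \code{hi > lo}.
#' @return Object of the same shape as \code{x}, values in \code{[0, 1]}.
#' @examples
#' normalizeRange(c(0.003, 0.01, 1), 0.003, 0.01)  # 0, 1, 1
#' @export
normalizeRange <- function(x, lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || !(hi > lo))
    stop("invalid normalization range: 'hi' must be greater than 'lo'")
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' Postprocessing operator p: min-max normalize then binarize
#'
#' The localization postprocessing function \emph{p}: min-max rescales an
#' activation map to \code{[0, 1]} and thresholds it at 0.5 (values >= 0.5
#' become 1). A constant map has no distinguished pixel and yields the
#' all-zero grid, so a flat map is never declared a whole-frame detection.
#' The output is invariant to positive affine rescaling of the input.
#'
#' @param map a \linkS4class{GrayMap} or a numeric matrix (any finite range).
#' @return Binary 0/1 matrix of the same size.
#' @examples
#' postprocessP(matrix(c(0.2, 0.4, 0.6, 0.2), 2))
#' @export
postprocessP <- function(map) {
  v <- if (is(map, "GrayMap")) map@values else map
  if (!all(is.finite(v))) stop("map must be finite-valued")
  rng <- range(v)
  if (rng[2] == rng[1]) return(matrix(0, nrow(v), ncol(v)))
  z <- (v - rng[1]) / (rng[2] - rng[1])
  matrix(as.numeric(z >= 0.5), nrow(v), ncol(v))
}

## ---- raster IO --------------------------------------------------------------

#' Read a colour frame from PNG or TIFF
#'
#' Reads an 8-bit RGB raster into a \linkS4class{ColorImage} (intensities
#' rescaled to 0-255). An alpha channel, if present, is dropped; grayscale
#' input is replicated across the three channels.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return A \linkS4class{ColorImage}.
#' @export
readColorImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", ext))
  if (is.matrix(a)) a <- array(a, c(dim(a), 3L))
  if (dim(a)[3] >= 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(a[, , 1], c(dim(a)[1:2], 3L))
  ColorImage(round(a[, , 1:3, drop = FALSE] * 255))
}

#' Write a colour frame as 8-bit PNG
#'
#' @param img a \linkS4class{ColorImage}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeColorImage <- function(img, path) {
  stopifnot(is(img, "ColorImage"))
  png::writePNG(img@pixels / 255, path)
  invisible(path)
}

#' Write a feature activation map
#'
#' Feature maps are written as 32-bit float TIFF (activation stored directly)
#' or as 8-bit grayscale PNG (\code{round(255 * activation)}).
#'
#' @param map a \linkS4class{GrayMap}.
#' @param path output path; extension selects the format.
#' @return Invisibly, \code{path}.
#' @export
writeGrayMap <- function(map, path) {
  stopifnot(is(map, "GrayMap"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(map@values, path, bits.per.sample = 32L)
  } else if (ext == "png") {
    png::writePNG(map@values, path)
  } else stop("unsupported raster format: ", ext)
  invisible(path)
}

#' Read a feature activation map written by [writeGrayMap()]
#'
#' @param path .tif/.tiff or .png path.
#' @return A \linkS4class{GrayMap}.
#' @export
readGrayMap <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", ext))
  if (!is.matrix(a)) a <- a[, , 1]
  GrayMap(pmin(pmax(a, 0), 1))
}

#' Write a binary mask as 8-bit PNG (0/255)
#'
#' @param mask a \linkS4class{RoiMask} or \linkS4class{ReferenceMask}.
#' @param path output .png path.
#' @return Invisibly, \code{path}.
#' @export
writeMask <- function(mask, path) {
  v <- mapValues(mask)
  png::writePNG(v, path)
  invisible(path)
}

#' Read a binary mask from an 8-bit raster (nonzero = foreground)
#'
#' @param path .png path.
#' @param as one of \code{"roi"} or \code{"reference"}.
#' @return A \linkS4class{RoiMask} or \linkS4class{ReferenceMask}.
#' @export
readMask <- function(path, as = c("roi", "reference")) {
  as <- match.arg(as)
  a <- png::readPNG(path)
  if (!is.matrix(a)) a <- a[, , 1]
  if (as == "roi") RoiMask(a >= 0.5) else ReferenceMask(a >= 0.5)
}
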