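#' @import methods
NULL

#' Colour endoscopy frame
#'
#' An 8-bit-scale RGB raster frame stored as an H x W x 3 numeric array with
#' intensities in \code{[0, 255]} (channel order red, green, blue). Values are
#' kept as doubles so that all per-pixel descriptor arithmetic happens in
#' floating point after byte extraction.
#'
#' @slot pixels numeric array, \code{H x W x 3}, values in \code{[0, 255]}.
#' @seealso [ColorImage()], [readColorImage()]
#' @export
setClass("ColorImage", representation(pixels = "array"))

setValidity("ColorImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (dim(p)[1] < 1L || dim(p)[2] < 1L)
    return("image must have H >= 1 and W >= 1")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("all intensities must be finite and in [0, 255]")
  TRUE
})

#' Single-channel activation map
#'
#' A feature activation map: an H x W grid of real values in \code{[0, 1]}
#' where pixel intensity encodes the local strength of one visual feature.
#'
#' @slot values numeric matrix with entries in \code{[0, 1]}.
#' @seealso [GrayMap()], [writeGrayMap()]
#' @export
setClass("GrayMap", representation(values = "matrix"))

setValidity("GrayMap", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v) || min(v) < 0 || max(v) > 1)
    return("all values must be finite and in [0, 1]")
  TRUE
})

#' Region-of-interest mask
#'
#' Binary H x W mask marking the visible organ area of a frame (1 = organ,
#' 0 = black border / overlay graphics).
#'
#' @slot values numeric 0/1 matrix.
#' @seealso [RoiMask()], [detectRoi()]
#' @export
setClass("RoiMask", representation(values = "matrix"))

setValidity("RoiMask", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v) || !all(v %in% c(0, 1)))
    return("mask must be binary (0/1)")
  TRUE
})

#' Annotated blood-area reference mask
#'
#' Binary H x W mask of the annotated blood area used as ground truth in
#' localization scoring.
#'
#' @slot values numeric 0/1 matrix.
#' @export
setClass("ReferenceMask", representation(values = "matrix"))

setValidity("ReferenceMask", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v) || !all(v %in% c(0, 1)))
    return("mask must be binary (0/1)")
  TRUE
})

#' Stack of the nine feature activation maps
#'
#' Ordered H x W x 9 array whose channel \code{c} holds the activation map of
#' descriptor \code{F<c>}; all activations are in \code{[0, 1]} and zero
#' outside the ROI they were computed under.
#'
#' @slot maps numeric array \code{H x W x 9}.
#' @seealso [computeAllDescriptors()]
#' @export
setClass("FeatureStack", representation(maps = "array"))

setValidity("FeatureStack", function(object) {
  m <- object@maps
  if (length(dim(m)) != 3L || dim(m)[3] != 9L)
    return("maps must be an H x W x 9 array")
  if (anyNA(m) || min(m) < 0 || max(m) > 1)
    return("all activations must be finite and in [0, 1]")
  TRUE
})

#' 12-channel CNN input tensor
#'
#' The fused network input: a 224 x 224 x 12 array in \code{[0, 1]} with
#' channel order R, G, B, F1..F9.
#'
#' @slot tensor numeric array \code{224 x 224 x 12}.
#' @seealso [toModelInput()]
#' @export
setClass("ModelInput", representation(tensor = "array"))

setValidity("ModelInput", function(object) {
  t <- object@tensor
  if (length(dim(t)) != 3L || !all(dim(t) == c(224L, 224L, 12L)))
    return("tensor must be 224 x 224 x 12")
  if (anyNA(t) || min(t) < 0 || max(t) > 1)
    return("all values must be finite and in [0, 1]")
  TRUE
})

#' First-layer convolution kernel bank
#'
#' Weights of the first convolutional layer of a CNN, stored as a
#' \code{k x k x C_in x C_out} array. Input depth is 3 for a plain RGB network
#' or 12 after fusion with the nine feature channels.
#'
#' @slot weights numeric array \code{k x k x C_in x C_out}.
#' @seealso [expandInputKernels()]
#' @export
setClass("KernelBank", representation(weights = "array"))

setValidity("KernelBank", function(object) {
  w <- object@weights
  if (length(dim(w)) != 4L) return("weights must be k x k x C_in x C_out")
  if (dim(w)[1] < 1L) return("kernel size k must be >= 1")
  if (!dim(w)[3] %in% c(3L, 12L)) return("C_in must be 3 or 12")
  if (anyNA(w)) return("weights must be finite")
  TRUE
})

#' Axis-aligned pixel bounding box
#'
#' Half-open pixel rectangle \code{[row0, row1) x [col0, col1)} in 0-based
#' coordinates, so that its area is exactly
#' \code{(row1 - row0) * (col1 - col0)}.
#'
#' @slot row0,col0,row1,col1 integer corner coordinates.
#' @seealso [maskToBbox()], [bboxIoU()]
#' @export
setClass("BoundingBox", representation(row0 = "integer", col0 = "integer",
                                       row1 = "integer", col1 = "integer"))

setValidity("BoundingBox", function(object) {
  if (object@row1 <= object@row0 || object@col1 <= object@col0)
    return("box must satisfy row1 > row0 and col1 > col0")
  if (object@row0 < 0L || object@col0 < 0L)
    return("box coordinates are 0-based and must be non-negative")
  TRUE
})

## ---- constructors -----------------------------------------------------------

#' @describeIn ColorImage-class Construct from an H x W x 3 array (values
#'   0-255) or from an H x W x 3 array in \code{[0, 1]} when
#'   \code{scale01 = TRUE}.
#' @param pixels numeric array.
#' @param scale01 logical; if \code{TRUE} input is in \code{[0, 1]} and is
#'   multiplied by 255.
#' @return A \linkS4class{ColorImage}.
#' @export
ColorImage <- function(pixels, scale01 = FALSE) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 3L))
  if (scale01) pixels <- pixels * 255
  new("ColorImage", pixels = pixels)
}

#' @describeIn GrayMap-class Construct from a numeric matrix in \code{[0, 1]}.
#' @param values numeric matrix.
#' @return A \linkS4class{GrayMap}.
#' @export
GrayMap <- function(values) new("GrayMap", values = values)

#' @describeIn RoiMask-class Construct from a 0/1 matrix (any nonzero entry is
#'   treated as 1).
#' @param values numeric or logical matrix.
#' @return A \linkS4class{RoiMask}.
#' @export
RoiMask <- function(values) {
  v <- matrix(as.numeric(values != 0), nrow(values), ncol(values))
  new("RoiMask", values = v)
}

#' @describeIn ReferenceMask-class Construct from a 0/1 matrix.
#' @param values numeric or logical matrix.
#' @return A \linkS4class{ReferenceMask}.
#' @export
ReferenceMask <- function(values) {
  v <- matrix(as.numeric(values != 0), nrow(values), ncol(values))
  new("ReferenceMask", values = v)
}

#' @describeIn FeatureStack-class Construct from an H x W x 9 array.
#' @param maps numeric array.
#' @return A \linkS4class{FeatureStack}.
#' @export
FeatureStack <- function(maps) new("FeatureStack", maps = maps)

#' @describeIn KernelBank-class Construct from a k x k x C_in x C_out array.
#' @param weights numeric array.
#' @return A \linkS4class{KernelBank}.
#' @export
KernelBank <- function(weights) new("KernelBank", weights = weights)

#' @describeIn BoundingBox-class Construct from 0-based half-open corner
#'   coordinates.
#' @param row0,col0,row1,col1 integer scalars.
#' @return A \linkS4class{BoundingBox}.
#' @export
BoundingBox <- function(row0, col0, row1, col1)
  new("BoundingBox", row0 = as.integer(row0), col0 = as.integer(col0),
      row1 = as.integer(row1), col1 = as.integer(col1))
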