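#' Pixel data accessor
#'
#' @param x an object with raster payload.
#' @return The underlying numeric array/matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "ColorImage", function(x) x@pixels)

#' Map values accessor
#'
#' @param x a \linkS4class{GrayMap}, \linkS4class{RoiMask} or
#'   \linkS4class{ReferenceMask}.
#' @return The underlying numeric matrix.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setMethod("mapValues", "GrayMap", function(x) x@values)
#' @rdname mapValues
#' @export
setMethod("mapValues", "RoiMask", function(x) x@values)
#' @rdname mapValues
#' @export
setMethod("mapValues", "ReferenceMask", function(x) x@values)

#' Feature map accessor
#'
#' @param x a \linkS4class{FeatureStack}.
#' @return The H x W x 9 activation array.
#' @export
setGeneric("featureMaps", function(x) standardGeneric("featureMaps"))

#' @rdname featureMaps
#' @export
setMethod("featureMaps", "FeatureStack", function(x) x@maps)

#' Kernel weights accessor
#'
#' @param x a \linkS4class{KernelBank}.
#' @return The k x k x C_in x C_out weight array.
#' @export
setGeneric("kernelWeights", function(x) standardGeneric("kernelWeights"))

#' @rdname kernelWeights
#' @export
setMethod("kernelWeights", "KernelBank", function(x) x@weights)

#' Input tensor accessor
#'
#' @param x a \linkS4class{ModelInput}.
#' @return The 224 x 224 x 12 tensor.
#' @export
setGeneric("inputTensor", function(x) standardGeneric("inputTensor"))

#' @rdname inputTensor
#' @export
setMethod("inputTensor", "ModelInput", function(x) x@tensor)

#' Bounding box corners
#'
#' @param x a \linkS4class{BoundingBox}.
#' @return Named integer vector \code{c(row0, col0, row1, col1)}.
#' @export
setGeneric("bboxCorners", function(x) standardGeneric("bboxCorners"))

#' @rdname bboxCorners
#' @export
setMethod("bboxCorners", "BoundingBox", function(x)
  c(row0 = x@row0, col0 = x@col0, row1 = x@row1, col1 = x@col1))

#' Pixel area of a bounding box
#'
#' @param x a \linkS4class{BoundingBox}.
#' @return Numeric scalar, \code{(row1 - row0) * (col1 - col0)}.
#' @export
setGeneric("bboxArea", function(x) standardGeneric("bboxArea"))

#' @rdname bboxArea
#' @export
setMethod("bboxArea", "BoundingBox", function(x)
  as.numeric(x@row1 - x@row0) * as.numeric(x@col1 - x@col0))

setMethod("dim", "ColorImage", function(x) dim(x@pixels)[1:2])
setMethod("dim", "GrayMap", function(x) dim(x@values))
setMethod("dim", "RoiMask", function(x) dim(x@values))
setMethod("dim", "ReferenceMask", function(x) dim(x@values))
setMethod("dim", "FeatureStack", function(x) dim(x@maps))

setMethod("show", "ColorImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ColorImage: %d x %d RGB frame, intensities [%.0f, %.0f]\n",
              d[1], d[2], min(object@pixels), max(object@pixels)))
})

setMethod("show", "GrayMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("GrayMap: %d x %d activation map, range [%.3f, %.3f]\n",
              d[1], d[2], min(object@values), max(object@values)))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("RoiMask: %d x %d, %d foreground pixels (%.1f%%)\n",
              d[1], d[2], sum(object@values),
              100 * mean(object@values)))
})

setMethod("show", "ReferenceMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("ReferenceMask: %d x %d, %d annotated pixels\n",
              d[1], d[2], sum(object@values)))
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@maps)
  cat(sprintf("FeatureStack: %d x %d x 9 (F1..F9)\n", d[1], d[2]))
  act <- apply(object@maps, 3, max)
  cat("  peak activation per channel:",
      paste(sprintf("F%d=%.2f", 1:9, act), collapse = " "), "\n")
})

setMethod("show", "ModelInput", function(object) {
  cat("ModelInput: 224 x 224 x 12 tensor (R, G, B, F1..F9)\n")
})

setMethod("show", "KernelBank", function(object) {
  d <- dim(object@weights)
  cat(sprintf("KernelBank: %d x %d kernels, %d input -> %d output channels\n",
              d[1], d[2], d[3], d[4]))
})

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox: rows [%d, %d) x cols [%d, %d), area %d px\n",
              object@row0, object@row1, object@col0, object@col1,
              (object@row1 - object@row0) * (object@col1 - object@col0)))
})
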