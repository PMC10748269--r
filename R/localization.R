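#' Feature-map bleeding localization (Fmap)
#'
#' Produces a binary bleeding-location map purely from the hand-crafted
#' descriptors, without any neural network inference: the activations of
#' features F1 to F7 are averaged and the result is passed through the
#' postprocessing operator \emph{p} ([postprocessP()]: min-max normalization
#' to \code{[0, 1]} followed by thresholding at 0.5).
#'
#' @param feats a \linkS4class{FeatureStack}.
#' @return Binary H x W matrix (1 = predicted blood).
#' @export
fmapLocalize <- function(feats) {
  stopifnot(is(feats, "FeatureStack"))
  m <- feats@maps
  avg <- (m[, , 1] + m[, , 2] + m[, , 3] + m[, , 4] + m[, , 5] +
          m[, , 6] + m[, , 7]) / 7
  postprocessP(avg)
}

#' Combine two localization maps
#'
#' Combines the Fmap localization with an externally supplied saliency map
#' (e.g. Grad-CAM or guided backpropagation output): each map is min-max
#' normalized to \code{[0, 1]}, the two are averaged, and the result is
#' postprocessed with \emph{p}. A constant map normalizes to all zeros and is
#' therefore neutral in the average.
#'
#' @param a,b \linkS4class{GrayMap}s or numeric matrices of the same size.
#' @return Binary H x W matrix.
#' @export
combineMaps <- function(a, b) {
  va <- if (is(a, "GrayMap")) a@values else a
  vb <- if (is(b, "GrayMap")) b@values else b
  if (!identical(dim(va), dim(vb)))
    stop("maps must share the same H x W dimensions")
  minmax <- function(v) {
    rng <- range(v)
    if (rng[2] == rng[1]) return(v * 0)
    (v - rng[1]) / (rng[2] - rng[1])
  }
  postprocessP((minmax(va) + minmax(vb)) / 2)
}

#' Tight bounding box of a binary mask
#'
#' Returns the tight axis-aligned bounding box of all nonzero pixels, in
#' 0-based half-open coordinates.
#'
#' @param mask binary matrix, \linkS4class{RoiMask} or
#'   \linkS4class{ReferenceMask}.
#' @return A \linkS4class{BoundingBox}, or \code{NULL} for an empty mask
#'   (an empty prediction scores IoU 0 against any non-empty reference).
#' @export
maskToBbox <- function(mask) {
  v <- if (is(mask, "RoiMask") || is(mask, "ReferenceMask"))
    mapValues(mask) else mask
  nz <- which(v != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(NULL)
  BoundingBox(min(nz[, 1]) - 1L, min(nz[, 2]) - 1L,
              max(nz[, 1]), max(nz[, 2]))
}

#' Intersection over union of two bounding boxes
#'
#' \code{IoU = area(a intersect b) / area(a union b)} with
#' \code{area(union) = area(a) + area(b) - area(intersection)}, on half-open
#' pixel rectangles so areas are exact integer counts.
#'
#' @param a,b \linkS4class{BoundingBox}es.
#' @return Real in \code{[0, 1]}; 1 iff the boxes are identical.
#' @examples
#' bboxIoU(BoundingBox(0, 0, 10, 10), BoundingBox(0, 5, 10, 15))  # 1/3
#' @export
bboxIoU <- function(a, b) {
  stopifnot(is(a, "BoundingBox"), is(b, "BoundingBox"))
  ih <- min(a@row1, b@row1) - max(a@row0, b@row0)
  iw <- min(a@col1, b@col1) - max(a@col0, b@col0)
  inter <- if (ih > 0 && iw > 0) as.numeric(ih) * as.numeric(iw) else 0
  union <- bboxArea(a) + bboxArea(b) - inter
  inter / union
}

#' Evaluate localization predictions by bounding-box IoU
#'
#' Scores each predicted binary map against its reference blood-area mask by
#' the IoU of their tight bounding boxes and averages over images. An empty
#' prediction against a non-empty reference scores 0; two empty masks score 1
#' (nothing to find, nothing found).
#'
#' @param predictions list of binary matrices.
#' @param references index-aligned list of \linkS4class{ReferenceMask}s or
#'   binary matrices.
#' @param ids optional character vector of image identifiers.
#' @return List with \code{meanIoU} (scalar) and \code{perImage}
#'   (data.frame: id, iou).
#' @export
evaluateLocalization <- function(predictions, references, ids = NULL) {
  if (length(predictions) != length(references))
    stop("predictions and references must have equal length")
  n <- length(predictions)
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_len(n))
  ious <- vapply(seq_len(n), function(i) {
    pb <- maskToBbox(predictions[[i]])
    rb <- maskToBbox(references[[i]])
    if (is.null(pb) && is.null(rb)) return(1)
    if (is.null(pb) || is.null(rb)) return(0)
    bboxIoU(pb, rb)
  }, numeric(1))
  list(meanIoU = if (n > 0) mean(ious) else NA_real_,
       perImage = data.frame(id = ids, iou = ious,
                             stringsAsFactors = FALSE))
}
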