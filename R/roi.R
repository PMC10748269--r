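#' Detect the region of interest of an endoscopic frame
#'
#' Endoscopic frames from analog capture show the organ inside a bright,
#' roughly circular or rounded-rectangular field of view surrounded by a
#' near-black border that often carries bright device overlay text. This
#' function recovers a binary mask of the organ area and discards both the
#' border and the overlays.
#'
#' The procedure: pixels with \code{max(r, g, b) > darkThreshold} are
#' candidate foreground (analog borders are near but not exactly zero);
#' the largest connected candidate component is kept (overlay text forms
#' small, isolated components in the border and is dropped here);
#' morphological closing with an elliptical kernel and hole filling close
#' specular gaps; a final erosion pulls the mask away from the border so
#' descriptors never sample the dark rim.
#'
#' @param img a \linkS4class{ColorImage}.
#' @param darkThreshold intensity (0-255 scale) above which a pixel is
#'   considered part of the visible field; default 12.
#' @param closeSize diameter in px of the disc kernel used for closing;
#'   default 15.
#' @param erodePx final erosion radius in px; default 3.
#' @return A \linkS4class{RoiMask}; exactly one connected foreground
#'   component.
#' @examples
#' frame <- generateFrame(sceneSpec(height = 96, width = 128, fovRadius = 40,
#'                                  seed = 1))
#' detectRoi(frame$image)
#' @export
detectRoi <- function(img, darkThreshold = 12, closeSize = 15, erodePx = 3) {
  stopifnot(is(img, "ColorImage"))
  px <- img@pixels
  bright <- pmax(channelMatrix(px, 1),
                 pmax(channelMatrix(px, 2),
                      channelMatrix(px, 3))) > darkThreshold
  if (!any(bright)) stop("empty ROI: frame is entirely near-black")
  fg <- matrix(as.numeric(bright), nrow(bright), ncol(bright))
  if (all(fg == 1)) return(RoiMask(fg))

  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  m <- matrix(as.numeric(lab == keep), nrow(fg), ncol(fg))

  kern <- EBImage::makeBrush(oddSize(closeSize), shape = "disc")
  m <- EBImage::closing(m, kern)
  m <- EBImage::fillHull(m)
  m <- EBImage::erode(m, EBImage::makeBrush(2L * erodePx + 1L, shape = "disc"))

  # closing/erosion can in principle split the mask; keep the largest piece
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    m <- matrix(as.numeric(lab == which.max(sizes)), nrow(m), ncol(m))
  }
  if (!any(m > 0)) stop("empty ROI: no visible field of view found")
  RoiMask(m)
}

# smallest odd integer >= n (EBImage disc brushes need odd sizes)
oddSize <- function(n) {
  n <- as.integer(n)
  if (n %% 2L == 0L) n + 1L else n
}
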