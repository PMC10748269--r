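#' Default descriptor parameters
#'
#' Returns the full parameter set of the nine feature descriptors F1-F9.
#' The F1 parameters (ratio-coefficient normalization window
#' \code{[0.003, 0.01]}, proximity exponent 5, final map window
#' \code{[0.02, 1.1]}, red floor 30) are the published values of the blood
#' colour region descriptor. The remaining descriptors share its pipeline
#' shape but their numeric parameters are this package's declared defaults,
#' chosen so that blood and mucosa fixtures from [generateFrame()] separate
#' cleanly; every value can be overridden per call or through a JSON config
#' (see [readRunConfig()]).
#'
#' Parameter groups:
#' \describe{
#'   \item{f1}{blood colour region: \code{c1Lo}, \code{c1Hi} (ratio window),
#'     \code{c2Exp} (green/blue proximity exponent), \code{mapLo},
#'     \code{mapHi} (final window), \code{rFloor} (red clearing threshold).}
#'   \item{f4}{red colour region: same fields, relaxed
#'     (\code{c1Lo = 0.0015}, \code{c2Exp = 2}).}
#'   \item{smooth}{F2/F5 smoothness gate: \code{window} (px, local std box),
#'     \code{stdLo}, \code{stdHi} (gray-std normalization window, 0-255
#'     scale).}
#'   \item{boundary}{F3/F6 clear-boundary test: \code{regionThreshold}
#'     (activation level defining a region), \code{edgeThreshold} (Sobel
#'     magnitude, 0-255 scale), \code{contourFrac} (fraction of contour
#'     pixels that must be edges).}
#'   \item{f7}{dispersed blood: \code{colorThreshold} (per-pixel blood-colour
#'     test on the F1 activation), \code{maxAreaFrac} (components larger than
#'     this fraction of the ROI are discarded).}
#'   \item{f8}{red domination: \code{redMargin} (excess of r over g and b),
#'     \code{highlightMin} (min(r,g,b) above this is an unclear highlight),
#'     \code{darkMax} (max(r,g,b) below this is unclear darkness),
#'     \code{fLo}, \code{fHi} (red-fraction normalization window; the 0.5
#'     output level corresponds exactly to a red fraction of 0.5).}
#'   \item{f9}{blur: \code{varLo}, \code{varHi} (global gray-variance window),
#'     \code{edgeThreshold} (Sobel magnitude defining an edge pixel),
#'     \code{eLo}, \code{eHi} (edge-fraction window).}
#' }
#'
#' @return Nested named list of parameters.
#' @export
descriptorDefaults <- function() {
  list(
    f1 = list(c1Lo = 0.003, c1Hi = 0.01, c2Exp = 5,
              mapLo = 0.02, mapHi = 1.1, rFloor = 30),
    f4 = list(c1Lo = 0.0015, c1Hi = 0.01, c2Exp = 2,
              mapLo = 0.02, mapHi = 1.1, rFloor = 30),
    smooth = list(window = 11, stdLo = 2, stdHi = 20),
    boundary = list(regionThreshold = 0.5, edgeThreshold = 100,
                    contourFrac = 0.2),
    f7 = list(colorThreshold = 0.5, maxAreaFrac = 0.01),
    f8 = list(redMargin = 20, highlightMin = 230, darkMax = 30,
              fLo = 0.25, fHi = 0.75),
    f9 = list(varLo = 100, varHi = 2000, edgeThreshold = 200,
              eLo = 0.01, eHi = 0.10)
  )
}

#' The nine descriptor identifiers
#'
#' @return Character vector \code{c("F1", ..., "F9")} in their fixed order.
#' @export
descriptorIds <- function() paste0("F", 1:9)

#' Human-readable descriptor names
#'
#' @return Named character vector mapping F1..F9 to their feature names.
#' @export
descriptorNames <- function() {
  c(F1 = "blood color region",
    F2 = "blood color region with a smooth surface",
    F3 = "blood region has a clear boundary",
    F4 = "red color region",
    F5 = "red color region with a smooth surface",
    F6 = "red region has a clear boundary",
    F7 = "dispersed blood color",
    F8 = "red color domination",
    F9 = "image is blurred")
}

# Shared F1/F4 colour-ratio pipeline, vectorized over the whole frame.
# r, g, b are byte-scale matrices; g and b are floored at 1 before division.
colorRatioMap <- function(px, roiv, c1Lo, c1Hi, c2Exp, mapLo, mapHi, rFloor) {
  r <- channelMatrix(px, 1)
  g <- pmax(channelMatrix(px, 2), 1)
  b <- pmax(channelMatrix(px, 3), 1)
  c1 <- pmin(r / b, r / g) / 255
  c1 <- pmax(c1, 0)
  c1 <- normalizeRange(c1, c1Lo, c1Hi)
  c2 <- 1 - abs(b - g) / 255
  fm <- normalizeRange(c1 * c2^c2Exp, mapLo, mapHi)
  fm[r < rFloor] <- 0
  fm[roiv == 0] <- 0
  fm
}

#' F1 blood colour region descriptor
#'
#' Computes the blood colour region activation map. Two coefficients are
#' combined per pixel: \code{c1 = min(r/b, r/g)/255}, clamped at zero and
#' normalized to the window \code{[0.003, 0.01]}, measures the excess of the
#' red channel over green and blue; \code{c2 = 1 - |b - g|/255} measures the
#' proximity of green and blue, which is typical of blood. The activation is
#' \code{norm(c1 * c2^5, 0.02, 1.1)}; pixels with \code{r < 30} and pixels
#' outside the ROI are cleared. Green and blue are floored at 1 before
#' division.
#'
#' @param img a \linkS4class{ColorImage}.
#' @param roi a \linkS4class{RoiMask} of the same size.
#' @param params parameter list, see [descriptorDefaults()] element
#'   \code{f1}.
#' @return A \linkS4class{GrayMap}.
#' @examples
#' px <- array(0, c(1, 2, 3))
#' px[1, 1, ] <- c(255, 1, 1)    # strong blood colour
#' px[1, 2, ] <- c(20, 10, 10)   # red floor clears this pixel
#' roi <- RoiMask(matrix(1, 1, 2))
#' mapValues(descriptorF1(ColorImage(px), roi))
#' @export
descriptorF1 <- function(img, roi, params = descriptorDefaults()$f1) {
  stopifnot(is(img, "ColorImage"), is(roi, "RoiMask"))
  stopIfShapeMismatch(img@pixels, roi@values, "image and roi")
  GrayMap(colorRatioMap(img@pixels, roi@values, params$c1Lo, params$c1Hi,
                        params$c2Exp, params$mapLo, params$mapHi,
                        params$rFloor))
}

# Smoothness gate used by F2/F5: 1 - norm(local std of gray intensity).
smoothnessGate <- function(px, p) {
  1 - normalizeRange(localStd(grayIntensity(px), p$window), p$stdLo, p$stdHi)
}

# Clear-boundary painting used by F3/F6: label regions of 'base' above the
# region threshold; a region is painted 1 if at least contourFrac of its
# contour pixels carry a strong image gradient.
clearBoundaryMap <- function(base, px, p) {
  b <- matrix(as.numeric(base > p$regionThreshold), nrow(base), ncol(base))
  out <- matrix(0, nrow(base), ncol(base))
  if (!any(b > 0)) return(out)
  lab <- EBImage::bwlabel(b)
  inner <- EBImage::erode(b, EBImage::makeBrush(3, shape = "box"))
  contour <- b > 0 & inner == 0
  if (!any(contour)) return(out)
  edge <- sobelMagnitude(grayIntensity(px)) > p$edgeThreshold
  labc <- lab[contour]
  frac <- tapply(as.numeric(edge[contour]), labc, mean)
  good <- as.integer(names(frac))[frac >= p$contourFrac]
  if (length(good)) out[lab %in% good] <- 1
  out
}

#' Compute one feature descriptor
#'
#' Dispatches to the per-feature algorithm for any of the nine descriptors:
#' \describe{
#'   \item{F1}{blood colour region ([descriptorF1()]).}
#'   \item{F2}{F1 activation gated by a local smoothness score
#'     \code{1 - norm(local std of gray intensity)} so only compact, smooth
#'     blood surfaces stay active.}
#'   \item{F3}{regions of F1 activation are painted 1 when at least a set
#'     fraction of their contour pixels lie on a strong Sobel edge; the map
#'     marks the region interior, i.e. where the clearly-bounded blood is.}
#'   \item{F4}{red colour region: the F1 pipeline with a relaxed ratio window
#'     and a weaker green/blue proximity exponent, accepting a wider range of
#'     shades of red.}
#'   \item{F5}{the F2 smoothness gate applied to the F4 activation.}
#'   \item{F6}{the F3 boundary test applied to the F4 activation.}
#'   \item{F7}{dispersed blood: a per-pixel blood-colour test (thresholded F1
#'     activation, before any area reasoning) with connected components larger
#'     than a fraction of the ROI area removed, keeping only spots, streaks
#'     and spray.}
#'   \item{F8}{red colour domination: the fraction f of ROI pixels passing a
#'     wide red test (r exceeding both g and b by a margin), excluding
#'     near-saturated highlights and near-black pixels, emitted as the
#'     constant map \code{norm(f, 0.25, 0.75)} so that a value above 0.5
#'     means red covers more than half the image.}
#'   \item{F9}{blur: \code{norm(v) * (1 - norm(e))} where v is the global
#'     gray-intensity variance and e the fraction of strong-edge pixels in
#'     the ROI; high variance with few edges indicates blur.}
#' }
#' F8 and F9 are image-level features emitted as constant-valued maps (inside
#' the ROI) so the 12-channel stacking contract stays uniform. Every output
#' is in \code{[0, 1]} and exactly zero outside the ROI.
#'
#' @param id one of \code{"F1"}..\code{"F9"}.
#' @param img a \linkS4class{ColorImage}.
#' @param roi a \linkS4class{RoiMask} of the same size.
#' @param params full parameter list as from [descriptorDefaults()].
#' @return A \linkS4class{GrayMap}.
#' @export
computeDescriptor <- function(id, img, roi, params = descriptorDefaults()) {
  if (!(is.character(id) && length(id) == 1L && id %in% descriptorIds()))
    stop("unknown descriptor id: ", paste(id, collapse = ","))
  stopifnot(is(img, "ColorImage"), is(roi, "RoiMask"))
  stopIfShapeMismatch(img@pixels, roi@values, "image and roi")
  px <- img@pixels
  roiv <- roi@values

  f1map <- function() mapValues(descriptorF1(img, roi, params$f1))
  f4map <- function() mapValues(descriptorF1(img, roi, params$f4))

  v <- switch(id,
    F1 = f1map(),
    F2 = f1map() * smoothnessGate(px, params$smooth),
    F3 = clearBoundaryMap(f1map(), px, params$boundary) * roiv,
    F4 = f4map(),
    F5 = f4map() * smoothnessGate(px, params$smooth),
    F6 = clearBoundaryMap(f4map(), px, params$boundary) * roiv,
    F7 = dispersedBloodMap(f1map(), roiv, params$f7),
    F8 = redDominationMap(px, roiv, params$f8),
    F9 = blurMap(px, roiv, params$f9)
  )
  GrayMap(clamp01(v))
}

# F7: keep the F1 activation only on small connected blood-colour components.
dispersedBloodMap <- function(f1v, roiv, p) {
  b <- matrix(as.numeric(f1v > p$colorThreshold), nrow(f1v), ncol(f1v))
  if (!any(b > 0)) return(b)
  lab <- EBImage::bwlabel(b)
  sizes <- tabulate(lab[lab > 0])
  maxArea <- p$maxAreaFrac * sum(roiv)
  small <- which(sizes <= maxArea)
  keep <- matrix(0, nrow(f1v), ncol(f1v))
  if (length(small)) keep[lab %in% small] <- 1
  f1v * keep
}

# F8: red colour domination as a constant map inside the ROI.
redDominationMap <- function(px, roiv, p) {
  r <- channelMatrix(px, 1); g <- channelMatrix(px, 2)
  b <- channelMatrix(px, 3)
  unclear <- (pmin(r, pmin(g, b)) > p$highlightMin) |
             (pmax(r, pmax(g, b)) < p$darkMax)
  valid <- roiv == 1 & !unclear
  f <- if (any(valid)) {
    red <- r > g + p$redMargin & r > b + p$redMargin
    mean(red[valid])
  } else 0
  normalizeRange(f, p$fLo, p$fHi) * roiv
}

# F9: global blur score as a constant map inside the ROI.
blurMap <- function(px, roiv, p) {
  gray <- grayIntensity(px)
  inside <- roiv == 1
  if (!any(inside)) return(roiv * 0)
  v <- stats::var(gray[inside])
  e <- mean((sobelMagnitude(gray) > p$edgeThreshold)[inside])
  normalizeRange(v, p$varLo, p$varHi) *
    (1 - normalizeRange(e, p$eLo, p$eHi)) * roiv
}

#' Compute the full nine-channel feature stack
#'
#' Runs [computeDescriptor()] for F1..F9 in order and stacks the activation
#' maps into a \linkS4class{FeatureStack}.
#'
#' @inheritParams computeDescriptor
#' @return A \linkS4class{FeatureStack} (H x W x 9).
#' @examples
#' frame <- generateFrame(sceneSpec(height = 96, width = 128, fovRadius = 40,
#'                                  seed = 1))
#' fs <- computeAllDescriptors(frame$image, frame$roi)
#' dim(fs)
#' @export
computeAllDescriptors <- function(img, roi, params = descriptorDefaults()) {
  stopifnot(is(img, "ColorImage"), is(roi, "RoiMask"))
  d <- dim(img@pixels)
  m <- array(0, c(d[1], d[2], 9L))
  for (i in 1:9)
    m[, , i] <- mapValues(computeDescriptor(descriptorIds()[i], img, roi,
                                            params))
  FeatureStack(m)
}
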