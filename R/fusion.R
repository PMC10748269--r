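#' Fuse RGB channels with the feature stack into a 12-channel image
#'
#' Channels 1-3 are r, g, b scaled to \code{[0, 1]} by division by 255;
#' channels 4-12 are the F1..F9 activation maps unchanged, so all twelve
#' channels share one dynamic range.
#'
#' @param img a \linkS4class{ColorImage}.
#' @param feats a \linkS4class{FeatureStack} of the same H x W.
#' @return Numeric array H x W x 12.
#' @export
stackChannels <- function(img, feats) {
  stopifnot(is(img, "ColorImage"), is(feats, "FeatureStack"))
  stopIfShapeMismatch(img@pixels, feats@maps, "image and feature stack")
  d <- dim(img@pixels)
  out <- array(0, c(d[1], d[2], 12L))
  out[, , 1:3] <- img@pixels / 255
  out[, , 4:12] <- feats@maps
  out
}

# Catmull-Rom (Keys, a = -0.5) cubic convolution kernel.
cubicKernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# Dense interpolation matrix mapping n source samples to nOut output samples
# under pixel-centre alignment: src = (dst + 0.5) * n/nOut - 0.5, with border
# samples clamped. Rows sum to 1, so constants are preserved exactly.
cubicWeights <- function(n, nOut) {
  W <- matrix(0, nOut, n)
  scale <- n / nOut
  for (i in seq_len(nOut)) {
    s <- (i - 0.5) * scale - 0.5        # 0-based source coordinate
    base <- floor(s)
    for (k in -1:2) {
      idx <- base + k                    # 0-based sample index
      w <- cubicKernel(s - idx)
      idx <- min(max(idx, 0), n - 1)     # clamp at borders
      W[i, idx + 1] <- W[i, idx + 1] + w
    }
  }
  W
}

#' Resize a matrix by separable cubic interpolation
#'
#' Catmull-Rom cubic convolution applied separably along rows and columns,
#' with replicate border handling. Constant inputs are reproduced exactly;
#' note cubic interpolation can overshoot near sharp transitions, so callers
#' that need a bounded range must clip.
#'
#' @param m numeric matrix.
#' @param height,width output size.
#' @return Numeric \code{height x width} matrix.
#' @export
resizeCubic <- function(m, height, width) {
  A <- cubicWeights(nrow(m), height)
  B <- cubicWeights(ncol(m), width)
  A %*% m %*% t(B)
}

#' Rescale a 12-channel image to the 224 x 224 x 12 model input
#'
#' Each channel is independently resized with cubic interpolation and then
#' clipped to \code{[0, 1]} (cubic overshoot near sharp feature edges would
#' otherwise leave the unit range).
#'
#' @param stacked numeric H x W x 12 array as produced by [stackChannels()].
#' @param size output spatial size (default 224).
#' @return A \linkS4class{ModelInput} when \code{size = 224}, otherwise a
#'   plain \code{size x size x 12} array.
#' @export
toModelInput <- function(stacked, size = 224L) {
  d <- dim(stacked)
  if (length(d) != 3L || d[3] != 12L)
    stop("input must be an H x W x 12 array")
  out <- array(0, c(size, size, 12L))
  A <- cubicWeights(d[1], size)
  B <- t(cubicWeights(d[2], size))
  for (c in 1:12) out[, , c] <- clamp01(A %*% stacked[, , c] %*% B)
  if (size == 224L) new("ModelInput", tensor = out) else out
}

#' Expand a 3-channel first-layer kernel bank to 12 input channels
#'
#' Adapts the first convolution layer of an RGB network to the fused
#' 12-channel input. The original three input slices are preserved
#' bit-exactly; the nine new slices are initialized either to zero (the
#' default, which makes the expansion function-preserving: the network output
#' is unchanged whenever the feature channels are zero) or to the mean of the
#' RGB slices (\code{"mean-replicate"}, a transfer-learning starting point
#' that gives the feature channels a non-trivial initial response).
#'
#' @param bank a \linkS4class{KernelBank} with \code{C_in = 3}.
#' @param extra number of appended input channels (default 9).
#' @param initMode \code{"zero"} or \code{"mean-replicate"}.
#' @return A \linkS4class{KernelBank} with \code{C_in = 3 + extra}.
#' @export
expandInputKernels <- function(bank, extra = 9L,
                               initMode = c("zero", "mean-replicate")) {
  stopifnot(is(bank, "KernelBank"))
  initMode <- match.arg(initMode)
  w <- bank@weights
  d <- dim(w)
  if (d[3] != 3L) stop("kernel bank must have C_in = 3")
  out <- array(0, c(d[1], d[2], d[3] + extra, d[4]))
  out[, , 1:3, ] <- w
  if (initMode == "mean-replicate") {
    mw <- (w[, , 1, , drop = FALSE] + w[, , 2, , drop = FALSE] +
           w[, , 3, , drop = FALSE]) / 3
    for (c in seq_len(extra)) out[, , 3L + c, ] <- mw[, , 1, ]
  }
  new("KernelBank", weights = out)
}

#' Forward pass of a single convolution layer
#'
#' Valid (no padding, stride 1) cross-correlation of a multi-channel input
#' with a kernel bank. Small and direct; used to verify that the zero-
#' initialized 12-channel expansion reproduces the 3-channel forward pass.
#'
#' @param input numeric H x W x C_in array.
#' @param bank a \linkS4class{KernelBank} with matching \code{C_in}.
#' @return Numeric (H - k + 1) x (W - k + 1) x C_out array.
#' @export
convForward <- function(input, bank) {
  stopifnot(is(bank, "KernelBank"))
  w <- bank@weights
  d <- dim(input)
  k <- dim(w)[1]
  if (length(d) != 3L || d[3] != dim(w)[3])
    stop("input channel count must match the kernel bank C_in")
  oh <- d[1] - k + 1L; ow <- d[2] - k + 1L
  if (oh < 1L || ow < 1L) stop("input smaller than kernel")
  out <- array(0, c(oh, ow, dim(w)[4]))
  for (o in seq_len(dim(w)[4]))
    for (c in seq_len(d[3]))
      for (di in seq_len(k))
        for (dj in seq_len(k))
          out[, , o] <- out[, , o] + w[di, dj, c, o] *
            input[di:(di + oh - 1L), dj:(dj + ow - 1L), c]
  out
}

#' Ensemble model scores by output averaging
#'
#' Model ensembling is performed by averaging the probability outputs of the
#' models included in the ensemble.
#'
#' @param scores numeric vector (or list) of per-model probabilities in
#'   \code{[0, 1]}. When each element is itself a vector of per-image scores,
#'   the element-wise mean across models is returned.
#' @return Averaged probability (scalar or vector).
#' @export
ensembleScores <- function(scores) {
  if (is.list(scores)) {
    if (length(scores) == 0L) stop("empty score list")
    lens <- vapply(scores, length, 1L)
    if (length(unique(lens)) != 1L)
      stop("all models must score the same images")
    m <- do.call(cbind, scores)
    if (anyNA(m) || min(m) < 0 || max(m) > 1)
      stop("scores must be probabilities in [0, 1]")
    return(rowMeans(m))
  }
  if (length(scores) == 0L) stop("empty score list")
  if (anyNA(scores) || min(scores) < 0 || max(scores) > 1)
    stop("scores must be probabilities in [0, 1]")
  mean(scores)
}
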