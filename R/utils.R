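# Internal raster helpers shared by the roi/descriptor/synthetic modules.

# Extract channel ch of an H x W x 3 array as a matrix (no dim dropping).
channelMatrix <- function(px, ch)
  matrix(px[, , ch], dim(px)[1], dim(px)[2])

# Mean-of-channels gray intensity on the 0-255 scale.
grayIntensity <- function(px)
  (channelMatrix(px, 1) + channelMatrix(px, 2) + channelMatrix(px, 3)) / 3

# Sobel gradient magnitude of a matrix (replicate boundary).
sobelMagnitude <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(m, kx, boundary = "replicate")
  gy <- EBImage::filter2(m, t(kx), boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

# Local standard deviation in a w x w box window (replicate boundary).
localStd <- function(m, w) {
  box <- matrix(1 / (w * w), w, w)
  mu <- EBImage::filter2(m, box, boundary = "replicate")
  mu2 <- EBImage::filter2(m * m, box, boundary = "replicate")
  sqrt(pmax(mu2 - mu * mu, 0))
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopIfShapeMismatch <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop(what, " must share the same H x W dimensions")
  invisible(TRUE)
}
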