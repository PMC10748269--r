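# Dataset preparation: sample balancing, examination-grouped fold
# assignment, and the image augmentation battery.
#
# A sample manifest is a data.frame with one row per image and columns
# sample_id, exam_id, label ("blood"/"non-blood"), image_path. All images of
# one sample belong to one examination.

checkManifest <- function(manifest) {
  need <- c("sample_id", "exam_id", "label", "image_path")
  if (!is.data.frame(manifest) || !all(need %in% names(manifest)))
    stop("manifest must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (!all(manifest$label %in% c("blood", "non-blood")))
    stop("label must be 'blood' or 'non-blood'")
  bad <- tapply(manifest$exam_id, manifest$sample_id,
                function(e) length(unique(e)) > 1)
  if (any(bad))
    stop("all images of one sample must share one examination")
  invisible(TRUE)
}

#' Balance small positive samples by cyclic duplication
#'
#' Blood-labelled samples with fewer than \code{minImages} images have their
#' image references duplicated cyclically until the count reaches
#' \code{minImages}, so that no positive bleeding case is drowned out by
#' larger cases during training. Non-blood samples are returned unchanged,
#' and no image is ever removed.
#'
#' @param manifest sample manifest data.frame (see above).
#' @param minImages minimum image count per blood sample; default 100.
#' @return Balanced manifest with the same columns.
#' @examples
#' m <- data.frame(sample_id = "s1", exam_id = "e1", label = "blood",
#'                 image_path = "img1.png")
#' nrow(balancePositiveSamples(m))  # 100
#' @export
balancePositiveSamples <- function(manifest, minImages = 100L) {
  checkManifest(manifest)
  parts <- split(manifest, manifest$sample_id)
  out <- lapply(parts, function(p) {
    if (p$label[1] != "blood" || nrow(p) >= minImages) return(p)
    idx <- rep(seq_len(nrow(p)), length.out = minImages)
    p[idx, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign examinations to cross-validation folds
#'
#' Randomly partitions examinations into \code{k} folds so that all images
#' from any given examination land in the same fold. The assignment is
#' balanced over exams (fold sizes differ by at most one exam) and is
#' deterministic under \code{seed}.
#'
#' @param manifest sample manifest data.frame.
#' @param k number of folds; default 5.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{exam_id}, \code{fold}.
#' @export
makeFolds <- function(manifest, k = 5L, seed = 1L) {
  checkManifest(manifest)
  exams <- unique(manifest$exam_id)
  if (length(exams) < k)
    stop("need at least k distinct examinations to build k folds")
  withSeed(seed, {
    shuffled <- sample(exams)
    data.frame(exam_id = shuffled,
               fold = rep(seq_len(k), length.out = length(shuffled)),
               stringsAsFactors = FALSE)
  })
}

#' Augmentation configuration
#'
#' Per-transform enable flags and magnitude ranges for the training-data
#' augmentation battery: rotation, horizontal/vertical flip, skew,
#' perspective, Gaussian blur, additive noise, hue distortion, saturation
#' distortion, and PCA colour augmentation. Each applied transform draws its
#' magnitude uniformly from its configured closed range. All ranges default
#' to mild, field-typical values; the transform set itself is fixed.
#'
#' @param rotate logical; rotation by an angle drawn from
#'   \code{rotateRange} (degrees).
#' @param rotateRange numeric length-2, default \code{c(-15, 15)}.
#' @param hflip,vflip logical; each flip applied with probability 0.5 when
#'   enabled.
#' @param skew logical; horizontal shear with factor from \code{skewRange}.
#' @param skewRange default \code{c(-0.1, 0.1)}.
#' @param perspective logical; random projective jitter of the four frame
#'   corners by a fraction of the frame size drawn from
#'   \code{perspectiveRange}.
#' @param perspectiveRange default \code{c(0, 0.05)}.
#' @param blur logical; Gaussian blur with sigma from \code{blurRange} (px).
#' @param blurRange default \code{c(0, 1.5)}.
#' @param noise logical; additive Gaussian noise with std from
#'   \code{noiseRange} (intensity units, 0-255 scale).
#' @param noiseRange default \code{c(0, 10)}.
#' @param hue logical; hue shift in degrees from \code{hueRange}.
#' @param hueRange default \code{c(-10, 10)}.
#' @param saturation logical; saturation scaling factor from
#'   \code{saturationRange}.
#' @param saturationRange default \code{c(0.8, 1.2)}.
#' @param pcaColor logical; eigenvalue-scaled shift along the principal
#'   components of the per-image RGB covariance, scale from
#'   \code{pcaColorRange}.
#' @param pcaColorRange default \code{c(0, 0.1)}.
#' @return Named list of class \code{"AugmentationConfig"}.
#' @export
augmentationConfig <- function(rotate = TRUE, rotateRange = c(-15, 15),
                               hflip = TRUE, vflip = TRUE,
                               skew = TRUE, skewRange = c(-0.1, 0.1),
                               perspective = TRUE,
                               perspectiveRange = c(0, 0.05),
                               blur = TRUE, blurRange = c(0, 1.5),
                               noise = TRUE, noiseRange = c(0, 10),
                               hue = TRUE, hueRange = c(-10, 10),
                               saturation = TRUE,
                               saturationRange = c(0.8, 1.2),
                               pcaColor = TRUE, pcaColorRange = c(0, 0.1)) {
  cfg <- list(rotate = rotate, rotateRange = rotateRange,
              hflip = hflip, vflip = vflip,
              skew = skew, skewRange = skewRange,
              perspective = perspective, perspectiveRange = perspectiveRange,
              blur = blur, blurRange = blurRange,
              noise = noise, noiseRange = noiseRange,
              hue = hue, hueRange = hueRange,
              saturation = saturation, saturationRange = saturationRange,
              pcaColor = pcaColor, pcaColorRange = pcaColorRange)
  for (nm in grep("Range$", names(cfg), value = TRUE)) {
    r <- cfg[[nm]]
    if (length(r) != 2L || r[2] < r[1])
      stop(nm, " must be a valid closed interval c(lo, hi)")
  }
  structure(cfg, class = "AugmentationConfig")
}

# Inverse-mapped projective warp with bilinear sampling; H maps output
# (row, col, 1) homogeneous coordinates to source coordinates. Out-of-frame
# samples replicate the border.
warpProjective <- function(px, H) {
  h <- dim(px)[1]; w <- dim(px)[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  sr <- H[1, 1] * rows + H[1, 2] * cols + H[1, 3]
  sc <- H[2, 1] * rows + H[2, 2] * cols + H[2, 3]
  sw <- H[3, 1] * rows + H[3, 2] * cols + H[3, 3]
  sr <- sr / sw; sc <- sc / sw
  r0 <- pmin(pmax(floor(sr), 1), h); r1 <- pmin(r0 + 1, h)
  c0 <- pmin(pmax(floor(sc), 1), w); c1 <- pmin(c0 + 1, w)
  fr <- pmin(pmax(sr - r0, 0), 1); fc <- pmin(pmax(sc - c0, 0), 1)
  out <- array(0, dim(px))
  for (ch in 1:3) {
    m <- px[, , ch]
    i00 <- m[cbind(c(r0), c(c0))]; i01 <- m[cbind(c(r0), c(c1))]
    i10 <- m[cbind(c(r1), c(c0))]; i11 <- m[cbind(c(r1), c(c1))]
    v <- (1 - fr) * ((1 - fc) * i00 + fc * i01) +
         fr * ((1 - fc) * i10 + fc * i11)
    out[, , ch] <- matrix(v, h, w)
  }
  out
}

# 3x3 homography mapping output pixel coords to source pixel coords given
# the four source corner positions corresponding to the output corners
# (rows of 'src' in order TL, TR, BL, BR as (row, col)).
cornersToHomography <- function(h, w, src) {
  dst <- rbind(c(1, 1), c(1, w), c(h, 1), c(h, w))
  A <- matrix(0, 8, 8); bvec <- numeric(8)
  for (i in 1:4) {
    r <- dst[i, 1]; cc <- dst[i, 2]
    A[2 * i - 1, ] <- c(r, cc, 1, 0, 0, 0, -src[i, 1] * r, -src[i, 1] * cc)
    A[2 * i, ]     <- c(0, 0, 0, r, cc, 1, -src[i, 2] * r, -src[i, 2] * cc)
    bvec[2 * i - 1] <- src[i, 1]
    bvec[2 * i] <- src[i, 2]
  }
  p <- solve(A, bvec)
  matrix(c(p[1:3], p[4:6], p[7], p[8], 1), 3, 3, byrow = TRUE)
}

#' Augment a colour frame
#'
#' Applies every enabled transform of an [augmentationConfig()] with a
#' magnitude drawn uniformly from its range, deterministically under
#' \code{seed}. Geometric transforms (rotation about the frame centre, skew,
#' perspective) are composed into one projective warp with bilinear
#' resampling; photometric transforms (blur, noise, hue, saturation, PCA
#' colour shift) follow. The output is rounded back to byte-valued
#' intensities and always preserves the input shape and the \code{[0, 255]}
#' range.
#'
#' @param img a \linkS4class{ColorImage}.
#' @param cfg an [augmentationConfig()].
#' @param seed integer RNG seed.
#' @return A \linkS4class{ColorImage}.
#' @export
augmentImage <- function(img, cfg = augmentationConfig(), seed = 1L) {
  stopifnot(is(img, "ColorImage"), inherits(cfg, "AugmentationConfig"))
  px <- img@pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  withSeed(seed, {
    # geometric: accumulate a forward corner displacement, then invert
    corners <- rbind(c(1, 1), c(1, w), c(h, 1), c(h, w))
    src <- corners
    geom <- FALSE
    if (isTRUE(cfg$rotate)) {
      ang <- stats::runif(1, cfg$rotateRange[1], cfg$rotateRange[2]) * pi / 180
      cr <- (h + 1) / 2; ccn <- (w + 1) / 2
      rot <- function(p) c(cr + cos(ang) * (p[1] - cr) - sin(ang) * (p[2] - ccn),
                           ccn + sin(ang) * (p[1] - cr) + cos(ang) * (p[2] - ccn))
      src <- t(apply(src, 1, rot)); geom <- TRUE
    }
    if (isTRUE(cfg$skew)) {
      s <- stats::runif(1, cfg$skewRange[1], cfg$skewRange[2])
      src[, 2] <- src[, 2] + s * (src[, 1] - (h + 1) / 2); geom <- TRUE
    }
    if (isTRUE(cfg$perspective)) {
      mag <- stats::runif(1, cfg$perspectiveRange[1], cfg$perspectiveRange[2])
      jit <- matrix(stats::runif(8, -mag, mag), 4, 2) *
        cbind(rep(h, 4), rep(w, 4))
      src <- src + jit; geom <- TRUE
    }
    if (geom) px <- warpProjective(px, cornersToHomography(h, w, src))
    if (isTRUE(cfg$hflip) && stats::runif(1) < 0.5)
      px <- px[, w:1, , drop = FALSE]
    if (isTRUE(cfg$vflip) && stats::runif(1) < 0.5)
      px <- px[h:1, , , drop = FALSE]
    if (isTRUE(cfg$blur)) {
      sigma <- stats::runif(1, cfg$blurRange[1], cfg$blurRange[2])
      if (sigma > 0.05)
        for (ch in 1:3) px[, , ch] <- EBImage::gblur(px[, , ch], sigma)
    }
    if (isTRUE(cfg$noise)) {
      sd <- stats::runif(1, cfg$noiseRange[1], cfg$noiseRange[2])
      if (sd > 0) px <- px + array(stats::rnorm(length(px), 0, sd), dim(px))
    }
    if (isTRUE(cfg$hue) || isTRUE(cfg$saturation)) {
      dh <- if (isTRUE(cfg$hue))
        stats::runif(1, cfg$hueRange[1], cfg$hueRange[2]) / 360 else 0
      ds <- if (isTRUE(cfg$saturation))
        stats::runif(1, cfg$saturationRange[1], cfg$saturationRange[2]) else 1
      rgb <- rbind(c(px[, , 1]), c(px[, , 2]), c(px[, , 3]))
      rgb <- pmin(pmax(rgb, 0), 255)
      hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
      hsv[1, ] <- (hsv[1, ] + dh) %% 1
      hsv[2, ] <- pmin(pmax(hsv[2, ] * ds, 0), 1)
      back <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ]))
      for (ch in 1:3) px[, , ch] <- matrix(back[ch, ], h, w)
    }
    if (isTRUE(cfg$pcaColor)) {
      scale <- stats::runif(1, cfg$pcaColorRange[1], cfg$pcaColorRange[2])
      if (scale > 0) {
        m <- cbind(c(px[, , 1]), c(px[, , 2]), c(px[, , 3]))
        ev <- eigen(stats::cov(m), symmetric = TRUE)
        alpha <- stats::rnorm(3, 0, scale)
        shift <- ev$vectors %*% (alpha * sqrt(pmax(ev$values, 0)))
        for (ch in 1:3) px[, , ch] <- px[, , ch] + shift[ch]
      }
    }
  })
  ColorImage(round(pmin(pmax(px, 0), 255)))
}
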