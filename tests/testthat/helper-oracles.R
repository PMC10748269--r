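# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: scalar per-pixel traces, brute-force
# pixel-set enumeration, and exhaustive threshold sweeps.

# Scalar per-pixel trace of the blood colour region descriptor, one pixel at
# a time, following the published pseudocode line by line under the
# element-wise-inverse reading of the ratio coefficient.
scalarF1 <- function(r, g, b, roi) {
  g <- max(g, 1)
  b <- max(b, 1)
  c1 <- min(r / b, r / g) / 255
  c1 <- max(c1, 0)
  c1 <- min(max((c1 - 0.003) / (0.01 - 0.003), 0), 1)
  c2 <- 1 - abs(b - g) / 255
  fm <- c1 * c2^5
  fm <- min(max((fm - 0.02) / (1.1 - 0.02), 0), 1)
  if (r < 30) fm <- 0
  if (roi == 0) fm <- 0
  fm
}

# Whole-image scalar oracle: explicit double loop over pixels.
scalarF1Image <- function(px, roiv) {
  h <- dim(px)[1]; w <- dim(px)[2]
  out <- matrix(0, h, w)
  for (i in seq_len(h))
    for (j in seq_len(w))
      out[i, j] <- scalarF1(px[i, j, 1], px[i, j, 2], px[i, j, 3],
                            roiv[i, j])
  out
}

# Pixel-set IoU of two half-open boxes by explicit enumeration of the
# integer pixels each box covers.
enumBoxIoU <- function(a, b) {
  ca <- bboxCorners(a); cb <- bboxCorners(b)
  pixelsOf <- function(cc) {
    grid <- expand.grid(row = seq(cc["row0"], cc["row1"] - 1),
                        col = seq(cc["col0"], cc["col1"] - 1))
    paste(grid$row, grid$col)
  }
  pa <- pixelsOf(ca); pb <- pixelsOf(cb)
  inter <- length(intersect(pa, pb))
  inter / (length(pa) + length(pb) - inter)
}

# O(n^2) pairwise ROC AUC oracle: P(pos > neg) + 0.5 P(pos == neg).
pairwiseAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Exhaustive operating-point sweep over all midpoint-style thresholds
# (every distinct score and one above all), conservative attainment.
sweepSensAtFpr <- function(scores, labels, fpr) {
  thr <- c(sort(unique(scores)), max(scores) + 1)
  best <- 0
  for (t in thr) {
    achievedFpr <- mean(scores[labels == 0] >= t)
    if (achievedFpr <= fpr)
      best <- max(best, mean(scores[labels == 1] >= t))
  }
  best
}

sweepSpecAtSens <- function(scores, labels, sens) {
  thr <- c(sort(unique(scores)), max(scores) + 1)
  best <- 0
  for (t in thr) {
    achievedSens <- mean(scores[labels == 1] >= t)
    if (achievedSens >= sens)
      best <- max(best, mean(scores[labels == 0] < t))
  }
  best
}

# Brute-force bounding box via a full min/max scan over nonzero pixels.
scanBbox <- function(m) {
  rows <- c(); cols <- c()
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      if (m[i, j] != 0) { rows <- c(rows, i); cols <- c(cols, j) }
  if (!length(rows)) return(NULL)
  BoundingBox(min(rows) - 1L, min(cols) - 1L, max(rows), max(cols))
}

# One colour channel of a ColorImage as a matrix.
channelOf <- function(img, ch) {
  px <- pixels(img)
  matrix(px[, , ch], dim(px)[1], dim(px)[2])
}

# Random byte image fixture.
randomImage <- function(h, w, seed) {
  set.seed(seed)
  ColorImage(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

# Flat single-colour frame with an all-ones ROI.
flatFrame <- function(h, w, color) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- color[ch]
  list(image = ColorImage(px), roi = RoiMask(matrix(1, h, w)))
}

# Scored-prediction fixture with adjustable class separation.
scoredFixture <- function(n, seed, shift = 0.3) {
  set.seed(seed)
  labels <- rep(c(0, 1), length.out = n)
  scores <- pmin(pmax(runif(n) + shift * labels - shift / 2, 0), 1)
  list(scores = scores, labels = labels)
}
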