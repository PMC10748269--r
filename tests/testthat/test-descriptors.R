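test_that("descriptorF1 matches the per-pixel scalar trace on single pixels", {
  onePixel <- function(r, g, b, roi = 1) {
    px <- array(c(r, g, b), c(1, 1, 3))
    mapValues(descriptorF1(ColorImage(px), RoiMask(matrix(roi, 1, 1))))[1, 1]
  }
  # strong blood colour: both coefficients saturate
  expect_equal(onePixel(255, 1, 1), (1 - 0.02) / (1.1 - 0.02))
  # red floor clears low-red pixels regardless of ratios
  expect_equal(onePixel(20, 1, 1), 0)
  expect_equal(onePixel(29, 2, 2), 0)
  # outside the ROI everything is cleared
  expect_equal(onePixel(255, 1, 1, roi = 0), 0)
  # neutral gray keeps a small residual activation under the inverse reading
  expect_equal(onePixel(100, 100, 100), scalarF1(100, 100, 100, 1))
  expect_equal(scalarF1(100, 100, 100, 1),
               ((1 / 255 - 0.003) / 0.007 - 0.02) / 1.08)
})

test_that("vectorized F1 equals the scalar oracle on random images", {
  for (seed in 1:10) {
    img <- randomImage(32, 32, seed)
    set.seed(seed + 500)
    roi <- RoiMask(matrix(rbinom(32 * 32, 1, 0.8), 32, 32))
    vec <- mapValues(descriptorF1(img, roi))
    ora <- scalarF1Image(pixels(img), mapValues(roi))
    expect_lt(max(abs(vec - ora)), 1e-9)
  }
})

test_that("F1 is non-decreasing in r for fixed g, b", {
  rs <- 30:255
  px <- array(0, c(1, length(rs), 3))
  px[1, , 1] <- rs; px[1, , 2] <- 40; px[1, , 3] <- 50
  act <- mapValues(descriptorF1(ColorImage(px),
                                RoiMask(matrix(1, 1, length(rs)))))
  expect_true(all(diff(c(act)) >= 0))
})

test_that("unknown ids and shape mismatches are rejected", {
  fr <- flatFrame(8, 8, c(100, 50, 50))
  expect_error(computeDescriptor("F10", fr$image, fr$roi), "unknown")
  expect_error(descriptorF1(fr$image, RoiMask(matrix(1, 4, 4))),
               "dimensions")
})

test_that("every channel is in [0,1] and zero outside the ROI", {
  for (seed in 1:6) {
    fr <- randomFrame(seed, nBlood = seed %% 3, height = 96, width = 128,
                      withDistractors = TRUE)
    fs <- featureMaps(computeAllDescriptors(fr$image, fr$roi))
    expect_true(all(fs >= 0 & fs <= 1))
    outside <- mapValues(fr$roi) == 0
    for (ch in 1:9) expect_true(all(fs[, , ch][outside] == 0))
  }
})

test_that("descriptors are pure functions of image and roi", {
  fr <- randomFrame(9, nBlood = 1, height = 96, width = 128)
  a <- featureMaps(computeAllDescriptors(fr$image, fr$roi))
  b <- featureMaps(computeAllDescriptors(fr$image, fr$roi))
  expect_identical(a, b)
})

test_that("F2 smoothness gate penalizes noisy blood surfaces", {
  blob <- list(center = c(48, 64), axes = c(25, 18))
  crisp <- generateFrame(sceneSpec(height = 96, width = 128, fovRadius = 45,
                                   bloodBlobs = list(blob), textureStd = 0,
                                   seed = 1))
  noisy <- crisp
  set.seed(21)
  px <- pixels(crisp$image)
  px <- pmin(pmax(px + array(rnorm(length(px), 0, 25), dim(px)), 0), 255)
  noisyImg <- ColorImage(round(px))
  inBlob <- mapValues(crisp$bloodMask) == 1
  f2crisp <- mapValues(computeDescriptor("F2", crisp$image, crisp$roi))
  f2noisy <- mapValues(computeDescriptor("F2", noisyImg, crisp$roi))
  expect_gt(mean(f2crisp[inBlob]), mean(f2noisy[inBlob]))
})

test_that("F3 paints clearly bounded blood regions on their interior", {
  blob <- list(center = c(48, 64), axes = c(25, 18))
  fr <- generateFrame(sceneSpec(height = 96, width = 128, fovRadius = 45,
                                bloodBlobs = list(blob), seed = 5))
  f3 <- mapValues(computeDescriptor("F3", fr$image, fr$roi))
  inBlob <- mapValues(fr$bloodMask) == 1
  expect_gt(mean(f3[inBlob]), 0.9)
  expect_lt(mean(f3[!inBlob]), 0.05)
})

test_that("F4 accepts a wider range of red than F1", {
  # a washed-out red that the strict blood window rejects
  fr <- flatFrame(16, 16, c(150, 80, 60))
  f1 <- mapValues(computeDescriptor("F1", fr$image, fr$roi))
  f4 <- mapValues(computeDescriptor("F4", fr$image, fr$roi))
  expect_true(all(f4 >= f1))
  expect_gt(mean(f4), mean(f1) + 0.1)
})

test_that("F7 ignores blood components larger than 1% of the ROI", {
  # one big blob: ~10% of the ROI -> excluded entirely
  big <- generateFrame(sceneSpec(height = 96, width = 128, fovRadius = 45,
                                 bloodBlobs = list(list(center = c(48, 64),
                                                        axes = c(20, 16))),
                                 seed = 2))
  f7 <- mapValues(computeDescriptor("F7", big$image, big$roi))
  expect_equal(sum(f7), 0)
  # small scattered spots well below 1% survive
  spots <- lapply(list(c(35, 50), c(60, 75), c(50, 90)), function(ctr)
    list(center = ctr, axes = c(3, 2)))
  small <- generateFrame(sceneSpec(height = 96, width = 128, fovRadius = 45,
                                   bloodBlobs = spots, seed = 2))
  f7s <- mapValues(computeDescriptor("F7", small$image, small$roi))
  inSpots <- mapValues(small$bloodMask) == 1
  expect_gt(mean(f7s[inSpots] > 0), 0.8)
})

test_that("F8 flags red domination above the 50% coverage level", {
  h <- 60; w <- 100
  px <- array(0, c(h, w, 3))
  # 60% wide-red columns, 40% neutral
  for (ch in 1:3) px[, , ch] <- 120
  px[, 1:60, 1] <- 170; px[, 1:60, 2] <- 90; px[, 1:60, 3] <- 90
  roi <- RoiMask(matrix(1, h, w))
  f8 <- mapValues(computeDescriptor("F8", ColorImage(px), roi))
  expect_true(all(f8 > 0.5))
  expect_equal(max(f8) - min(f8), 0)  # constant map
  # 40% red coverage falls below the 0.5 output level
  px2 <- px; px2[, 41:60, 1] <- 120; px2[, 41:60, 2] <- 120
  px2[, 41:60, 3] <- 120
  f8lo <- mapValues(computeDescriptor("F8", ColorImage(px2), roi))
  expect_true(all(f8lo < 0.5))
})

test_that("F8 excludes near-saturated highlights from the red fraction", {
  h <- 40; w <- 40
  px <- array(240, c(h, w, 3))          # near-saturated everywhere
  px[1:20, , 1] <- 170; px[1:20, , 2] <- 90; px[1:20, , 3] <- 90
  roi <- RoiMask(matrix(1, h, w))
  f8 <- mapValues(computeDescriptor("F8", ColorImage(px), roi))
  # highlights are not counted as non-red: red fraction is 1 of the clear px
  expect_true(all(f8 == 1))
})

test_that("F9 rises under Gaussian blur of a sharp scene", {
  h <- 96; w <- 96
  sq <- 16
  board <- 255 * ((floor((row(matrix(0, h, w)) - 1) / sq) +
                   floor((col(matrix(0, h, w)) - 1) / sq)) %% 2)
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- board
  roi <- RoiMask(matrix(1, h, w))
  sharp <- mapValues(computeDescriptor("F9", ColorImage(px), roi))[1, 1]
  for (ch in 1:3) px[, , ch] <- EBImage::gblur(board, 5)
  px <- pmin(pmax(px, 0), 255)
  blurred <- mapValues(computeDescriptor("F9", ColorImage(px), roi))[1, 1]
  expect_gt(blurred, sharp)
})

test_that("the full stack has shape H x W x 9 and sensible channel content", {
  dark <- flatFrame(32, 48, c(0, 0, 0))
  fs0 <- computeAllDescriptors(dark$image, dark$roi)
  expect_equal(dim(fs0), c(32, 48, 9))
  expect_equal(sum(featureMaps(fs0)[, , 1:8]), 0)  # F9 may read 0 variance

  fr <- generateFrame(sceneSpec(height = 96, width = 128, fovRadius = 45,
                                bloodBlobs = list(list(center = c(48, 64),
                                                       axes = c(14, 10))),
                                seed = 8))
  fs <- featureMaps(computeAllDescriptors(fr$image, fr$roi))
  # interior of the blob, away from the boundary band the smoothness window
  # straddles
  core <- EBImage::erode(mapValues(fr$bloodMask),
                         EBImage::makeBrush(11, "disc")) == 1
  for (ch in 1:3) expect_gt(mean(fs[, , ch][core]), 0.5)
  expect_equal(max(fs[, , 8]) - min(fs[, , 8][mapValues(fr$roi) == 1]), 0)
})

test_that("blood and mucosa colours separate on the F1 activation", {
  fr <- generateFrame(sceneSpec(height = 96, width = 128, fovRadius = 45,
                                bloodBlobs = list(list(center = c(48, 64),
                                                       axes = c(14, 10))),
                                seed = 12))
  f1 <- mapValues(descriptorF1(fr$image, fr$roi))
  inBlob <- mapValues(fr$bloodMask) == 1
  mucosa <- mapValues(fr$roi) == 1 & !inBlob
  expect_gt(min(f1[inBlob]), 0.6)
  expect_lt(mean(f1[mucosa]), 0.3)
  # mucosa never reaches the region threshold used by F3/F6/F7
  expect_lt(max(f1[mucosa]), 0.5)
})
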