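makeManifest <- function(sizes, labels, examsPerSample = NULL) {
  rows <- lapply(seq_along(sizes), function(i) {
    data.frame(sample_id = sprintf("s%02d", i),
               exam_id = if (is.null(examsPerSample))
                 sprintf("e%02d", i) else examsPerSample[i],
               label = labels[i],
               image_path = sprintf("s%02d_img%03d.png", i,
                                    seq_len(sizes[i])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("balancing duplicates small blood samples cyclically to 100", {
  m <- makeManifest(c(1, 5, 250, 3), c("blood", "blood", "blood",
                                       "non-blood"))
  out <- balancePositiveSamples(m)
  sizes <- table(out$sample_id)
  expect_equal(as.integer(sizes[c("s01", "s02", "s03", "s04")]),
               c(100, 100, 250, 3))
  # cyclic duplication: every original image still present, in proportion
  s2 <- out$image_path[out$sample_id == "s02"]
  expect_equal(as.integer(table(s2)), rep(20, 5))
  s1 <- out$image_path[out$sample_id == "s01"]
  expect_equal(unique(s1), "s01_img001.png")
  # negatives untouched, nothing removed
  expect_equal(out[out$sample_id == "s04", ], m[m$sample_id == "s04", ],
               ignore_attr = TRUE)
  expect_true(all(m$image_path %in% out$image_path))
})

test_that("balancing leaves large blood samples and all negatives alone", {
  m <- makeManifest(c(250, 1), c("blood", "non-blood"))
  out <- balancePositiveSamples(m)
  expect_equal(nrow(out), 251)
  expect_gte(sum(out$label == "blood"),
             100 * length(unique(m$sample_id[m$label == "blood"])) *
               0 + 250)
})

test_that("total positives after balancing reach 100 per blood sample", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    sizes <- sample(c(1, 2, 5, 50, 120, 300), n, replace = TRUE)
    labels <- sample(c("blood", "non-blood"), n, replace = TRUE)
    out <- balancePositiveSamples(makeManifest(sizes, labels))
    nblood <- sum(labels == "blood")
    expect_gte(sum(out$label == "blood"), 100 * nblood)
    expect_equal(sum(out$label == "non-blood"),
                 sum(sizes[labels == "non-blood"]))
  }
})

test_that("makeFolds partitions exams, keeps exams whole, and is seeded", {
  m <- makeManifest(rep(2, 10), rep(c("blood", "non-blood"), 5))
  f <- makeFolds(m, k = 5, seed = 42)
  expect_setequal(f$exam_id, unique(m$exam_id))
  expect_true(all(table(f$fold) >= 1))
  expect_identical(f, makeFolds(m, k = 5, seed = 42))
  expect_false(identical(f$exam_id, makeFolds(m, k = 5, seed = 43)$exam_id))
  expect_error(makeFolds(makeManifest(c(2, 2), c("blood", "blood")), k = 5),
               "at least k")
})

test_that("no exam's images ever span two folds", {
  set.seed(4)
  for (rep in 1:100) {
    nex <- sample(5:12, 1)
    nsamp <- sample(nex:(2 * nex), 1)
    exams <- sprintf("e%02d", sample(nex, nsamp, replace = TRUE))
    exams[1:nex] <- sprintf("e%02d", 1:nex)   # every exam present
    m <- makeManifest(sample(1:4, nsamp, replace = TRUE),
                      sample(c("blood", "non-blood"), nsamp, replace = TRUE),
                      examsPerSample = exams)
    f <- makeFolds(m, k = 5, seed = rep)
    merged <- merge(m, f, by = "exam_id")
    spread <- tapply(merged$fold, merged$exam_id,
                     function(x) length(unique(x)))
    expect_true(all(spread == 1))
  }
})

test_that("augmentation is identity when disabled and deterministic under seed", {
  img <- randomFrame(6, nBlood = 1, height = 72, width = 96)$image
  off <- augmentationConfig(rotate = FALSE, hflip = FALSE, vflip = FALSE,
                            skew = FALSE, perspective = FALSE, blur = FALSE,
                            noise = FALSE, hue = FALSE, saturation = FALSE,
                            pcaColor = FALSE)
  expect_equal(pixels(augmentImage(img, off, seed = 1)), pixels(img))
  cfg <- augmentationConfig()
  a <- augmentImage(img, cfg, seed = 7)
  b <- augmentImage(img, cfg, seed = 7)
  expect_identical(pixels(a), pixels(b))
  expect_false(identical(pixels(a),
                         pixels(augmentImage(img, cfg, seed = 8))))
})

test_that("flips are involutions under a fixed seed", {
  img <- randomFrame(7, nBlood = 0, height = 72, width = 96)$image
  fl <- augmentationConfig(rotate = FALSE, hflip = TRUE, vflip = TRUE,
                           skew = FALSE, perspective = FALSE, blur = FALSE,
                           noise = FALSE, hue = FALSE, saturation = FALSE,
                           pcaColor = FALSE)
  once <- augmentImage(img, fl, seed = 3)
  twice <- augmentImage(once, fl, seed = 3)
  expect_equal(pixels(twice), pixels(img))
})

test_that("augmentation preserves shape and byte range", {
  img <- randomFrame(8, nBlood = 1, height = 72, width = 96)$image
  for (seed in 1:5) {
    out <- pixels(augmentImage(img, augmentationConfig(), seed = seed))
    expect_equal(dim(out), c(72, 96, 3))
    expect_true(all(out >= 0 & out <= 255))
    expect_true(all(out == round(out)))
  }
})

test_that("augmentation config rejects invalid ranges", {
  expect_error(augmentationConfig(rotateRange = c(10, -10)), "interval")
  expect_error(augmentationConfig(blurRange = 2), "interval")
})

test_that("manifest validation catches cross-exam samples and bad labels", {
  m <- makeManifest(c(2, 2), c("blood", "non-blood"))
  m$exam_id[2] <- "e99"
  expect_error(balancePositiveSamples(m), "one examination")
  m2 <- makeManifest(c(2, 2), c("blood", "maybe"))
  expect_error(makeFolds(m2, k = 2), "label")
})
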