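test_that("confusionCounts enumerates the four cells at the 0.5 threshold", {
  labels <- c(1, 1, 0, 0)
  expect_equal(confusionCounts(c(1, 1, 0, 0), labels),
               c(TP = 2, FP = 0, TN = 2, FN = 0))
  expect_equal(confusionCounts(rep(0, 4), labels),
               c(TP = 0, FP = 0, TN = 2, FN = 2))
  # ties at the threshold count as positive predictions
  expect_equal(confusionCounts(c(0.5, 0.4, 0.5, 0.4), labels),
               c(TP = 1, FP = 1, TN = 1, FN = 1))
  # random cases against a per-item loop
  set.seed(5)
  for (rep in 1:10) {
    s <- runif(10); l <- rbinom(10, 1, 0.5)
    cc <- confusionCounts(s, l)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in 1:10) {
      if (s[i] >= 0.5 && l[i] == 1) tp <- tp + 1
      if (s[i] >= 0.5 && l[i] == 0) fp <- fp + 1
      if (s[i] < 0.5 && l[i] == 0) tn <- tn + 1
      if (s[i] < 0.5 && l[i] == 1) fn <- fn + 1
    }
    expect_equal(unname(cc), c(tp, fp, tn, fn))
    expect_equal(sum(cc), 10)
  }
})

test_that("fBeta follows its formula with the zero convention", {
  expect_equal(fBeta(0.5, 1, beta = 2), 5 * 0.5 / (4 * 0.5 + 1))
  for (p in c(0.1, 0.5, 0.9)) {
    expect_equal(fBeta(p, p, beta = 1), p)
    expect_equal(fBeta(p, p, beta = 2), p)
  }
  expect_equal(fBeta(1, 0), 0)
  expect_equal(fBeta(0, 1), 0)
  expect_equal(fBeta(0, 0), 0)
})

test_that("rocAuc handles separation, ties, and matches the pairwise oracle", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAuc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(rocAuc(c(0.1, 0.9), c(1, 1)), "both classes")
  for (seed in 1:20) {
    fx <- scoredFixture(200, seed)
    # scores quantized to force ties
    q <- round(fx$scores * 20) / 20
    expect_equal(rocAuc(q, fx$labels), pairwiseAuc(q, fx$labels),
                 tolerance = 1e-12)
  }
})

test_that("rocAuc agrees with pROC as an external cross-check", {
  skip_if_not_installed("pROC")
  fx <- scoredFixture(300, seed = 77)
  ref <- as.numeric(pROC::auc(pROC::roc(fx$labels, fx$scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(rocAuc(fx$scores, fx$labels), ref, tolerance = 1e-12)
})

test_that("complement symmetry holds for tie-free scores", {
  set.seed(8)
  scores <- sample(seq(0.001, 0.999, length.out = 100))
  labels <- rbinom(100, 1, 0.5)
  labels[1:2] <- c(0, 1)
  expect_equal(rocAuc(scores, labels) + rocAuc(1 - scores, labels), 1)
})

test_that("operating points match the exhaustive sweep oracle", {
  for (seed in 1:10) {
    fx <- scoredFixture(50, seed, shift = 0.4)
    for (fpr in c(0.02, 0.1, 0.3))
      expect_equal(as.numeric(sensAtFpr(fx$scores, fx$labels, fpr)),
                   sweepSensAtFpr(fx$scores, fx$labels, fpr))
    for (sens in c(0.5, 0.9, 0.99))
      expect_equal(specAtSens(fx$scores, fx$labels, sens),
                   sweepSpecAtSens(fx$scores, fx$labels, sens))
  }
  # perfect and anti-perfect separation
  s <- c(0.9, 0.8, 0.2, 0.1); l <- c(1, 1, 0, 0)
  expect_equal(as.numeric(sensAtFpr(s, l, 0.01)), 1)
  expect_equal(specAtSens(s, l, 0.95), 1)
  expect_equal(as.numeric(sensAtFpr(1 - s, l, 0.25)), 0)
  # constant scores: forcing sensitivity misclassifies every negative
  expect_equal(specAtSens(rep(0.5, 6), c(1, 0, 1, 0, 1, 0), 0.95), 0)
})

test_that("operating points are monotone in their arguments", {
  fx <- scoredFixture(120, seed = 33)
  fprs <- c(0.01, 0.05, 0.1, 0.3, 0.6)
  sens <- vapply(fprs, function(f)
    as.numeric(sensAtFpr(fx$scores, fx$labels, f)), numeric(1))
  expect_true(all(diff(sens) >= 0))
  lvls <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  specs <- vapply(lvls, function(s)
    specAtSens(fx$scores, fx$labels, s), numeric(1))
  expect_true(all(diff(specs) <= 0))
})

test_that("degenerate operating-point resolution is flagged", {
  fx <- scoredFixture(40, seed = 2)  # 20 negatives < 1/0.001
  expect_true(isTRUE(attr(sensAtFpr(fx$scores, fx$labels, 0.001),
                          "degenerateResolution")))
})

test_that("fullReport composes all thirteen metrics consistently", {
  fx <- scoredFixture(200, seed = 50, shift = 0.6)
  rep <- fullReport(fx$scores, fx$labels)
  expect_named(rep, c("ROCAUC", "F1", "F2", "sensitivity", "specificity",
                      "precision", "accuracy", "sens@0.01", "sens@0.001",
                      "sens@0.0001", "spec@0.95", "spec@0.99", "spec@0.999"))
  expect_true(all(unlist(rep) >= 0 & unlist(rep) <= 1))
  cc <- confusionCounts(fx$scores, fx$labels)
  expect_equal(rep$accuracy, (cc["TP"] + cc["TN"]) / sum(cc),
               ignore_attr = TRUE)
  expect_equal(rep$sensitivity, cc["TP"] / (cc["TP"] + cc["FN"]),
               ignore_attr = TRUE)
  expect_equal(rep$specificity, cc["TN"] / (cc["TN"] + cc["FP"]),
               ignore_attr = TRUE)
  expect_equal(rep$F1, fBeta(rep$precision, rep$sensitivity, 1))
  expect_equal(rep$F2, fBeta(rep$precision, rep$sensitivity, 2))
})
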