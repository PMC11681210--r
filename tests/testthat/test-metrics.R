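test_that("hand-computed metrics match the formulas", {
  f <- generateConfusionFixture(10, 80, 5, 5, seed = 2)
  cc <- confusionCounts(f$truth, f$pred)
  expect_equal(unname(confusionVector(cc)), c(10, 80, 5, 5))
  rep <- computeMetrics(cc)
  expect_equal(rep@accuracy, 0.90)
  expect_equal(rep@precision, 2 / 3)
  expect_equal(rep@sensitivity, 2 / 3)
  expect_equal(rep@specificity, 16 / 17)
  expect_equal(rep@dice, 2 / 3)
  expect_equal(rep@iou, 0.5)
  expect_length(rep@flags, 0)
})

test_that("perfect agreement and perfect disagreement are recognized", {
  set.seed(4)
  m <- matrix(rbinom(100, 1, 0.4), 10, 10)
  agree <- confusionCounts(m, m)
  expect_equal(agree@pIncorrect + agree@nIncorrect, 0)
  rep <- computeMetrics(agree)
  for (f in c("accuracy", "precision", "sensitivity", "specificity",
              "dice", "iou"))
    expect_equal(slot(rep, f), 1)
  flip <- confusionCounts(m, 1 - m)
  expect_equal(flip@pCorrect + flip@nCorrect, 0)
})

test_that("vectorized counts and ratios agree with the brute-force oracle", {
  set.seed(99)
  for (i in 1:25) {
    h <- sample(4:24, 1)
    w <- sample(4:24, 1)
    pair <- random_mask_pair(h, w)
    cc <- confusionCounts(pair$truth, pair$pred)
    ref <- brute_confusion(pair$truth, pair$pred)
    expect_equal(unname(confusionVector(cc)), unname(as.numeric(ref)))
    rep <- computeMetrics(cc)
    tp <- ref["TP"]; tn <- ref["TN"]; fp <- ref["FP"]; fn <- ref["FN"]
    if (tp + fp > 0) expect_equal(rep@precision, unname(tp / (tp + fp)),
                                  tolerance = 1e-10)
    if (!is.na(rep@dice) && !is.na(rep@iou))
      expect_equal(rep@dice, 2 * rep@iou / (1 + rep@iou),
                   tolerance = 1e-12)
  }
})

test_that("undefined ratios are flagged rather than coerced", {
  cc <- confusionCounts(matrix(0, 4, 4), matrix(0, 4, 4))
  rep <- computeMetrics(cc)
  expect_equal(rep@accuracy, 1)
  expect_true(is.na(rep@precision))
  expect_true(is.na(rep@sensitivity))
  expect_setequal(rep@flags, c("precision", "sensitivity", "dice", "iou"))
  expect_error(confusionCounts(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               class = "ts_validation_error")
  expect_error(confusionCounts(matrix(0, 2, 2), matrix(0, 2, 3)),
               class = "ts_validation_error")
})

test_that("binary cross-entropy matches direct evaluation", {
  set.seed(3)
  truth <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_equal(bceLoss(truth, matrix(0.5, 8, 8)), log(2), tolerance = 1e-9)
  # exact prediction: only the clipping floor remains
  expect_lt(bceLoss(truth, truth + 0), 1e-6)
  # four-pixel case summed by hand from the formula
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  p <- matrix(c(0.9, 0.2, 0.6, 0.4), 2, 2)
  ref <- -(log(0.9) + log(1 - 0.2) + log(0.6) + log(1 - 0.4)) / 4
  expect_equal(bceLoss(y, p), ref, tolerance = 1e-10)
  expect_error(bceLoss(y, matrix(1.2, 2, 2)), class = "ts_validation_error")
})

test_that("micro aggregation pools counts before applying the formulas", {
  set.seed(21)
  p1 <- random_mask_pair(8, 8)
  p2 <- random_mask_pair(6, 10)
  one <- aggregateOverDataset(list(p1))
  direct <- computeMetrics(confusionCounts(p1$truth, p1$pred))
  expect_equal(one@dice, direct@dice)
  # homogeneity: duplicating a pair changes nothing under micro pooling
  two <- aggregateOverDataset(list(p1, p1))
  expect_equal(metricsAsDataFrame(two)[, 1:6],
               metricsAsDataFrame(one)[, 1:6])
  # mixed pairs equal the formulas applied to summed counts
  mix <- aggregateOverDataset(list(p1, p2))
  s <- brute_confusion(p1$truth, p1$pred) + brute_confusion(p2$truth, p2$pred)
  expect_equal(mix@iou, unname(s["TP"] / (s["TP"] + s["FP"] + s["FN"])),
               tolerance = 1e-12)
  expect_error(aggregateOverDataset(list()), class = "ts_validation_error")
  # macro averages per-image metrics instead
  macro <- aggregateOverDataset(list(p1, p2), mode = "macro")
  d1 <- computeMetrics(confusionCounts(p1$truth, p1$pred))@dice
  d2 <- computeMetrics(confusionCounts(p2$truth, p2$pred))@dice
  expect_equal(macro@dice, mean(c(d1, d2)))
})

test_that("raising the threshold never increases TP or FP", {
  set.seed(12)
  prob <- matrix(runif(20 * 20), 20, 20)
  truth <- matrix(rbinom(400, 1, 0.3), 20, 20)
  prev_tp <- Inf
  prev_fp <- Inf
  for (thr in seq(0.1, 0.9, by = 0.1)) {
    cc <- confusionCounts(truth, thresholdProbabilities(prob, thr))
    expect_lte(cc@pCorrect, prev_tp)
    expect_lte(cc@pIncorrect, prev_fp)
    prev_tp <- cc@pCorrect
    prev_fp <- cc@pIncorrect
  }
})
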