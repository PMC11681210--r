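test_that("phantom generation is a pure function of (spec, seed)", {
  spec <- phantomSpec(imageSize = 64, nVessels = 2, seed = 42)
  s1 <- generatePhantom(spec)
  s2 <- generatePhantom(spec)
  expect_identical(sampleImage(s1), sampleImage(s2))
  expect_identical(sampleMask(s1), sampleMask(s2))
  s3 <- generatePhantom(phantomSpec(imageSize = 64, nVessels = 2, seed = 43))
  expect_false(identical(sampleImage(s1), sampleImage(s3)))
})

test_that("full-clot phantom mask equals an independent ellipse scan", {
  spec <- phantomSpec(imageSize = 64, nVessels = 1, clotFraction = 1.0,
                      noiseSigma = 0, seed = 5)
  s <- generatePhantom(spec)
  g <- sampleMeta(s)$vessels
  ref <- matrix(0L, 64, 64)
  for (i in 1:64) {
    for (j in 1:64) {
      u <- (i - g$cr) * cos(g$theta) + (j - g$cc) * sin(g$theta)
      w <- -(i - g$cr) * sin(g$theta) + (j - g$cc) * cos(g$theta)
      if ((u / g$a)^2 + (w / g$b)^2 <= 1) ref[i, j] <- 1L
    }
  }
  expect_identical(sampleMask(s), ref)
  expect_gt(sum(sampleMask(s)), 0)
})

test_that("empty scene with zero background and noise is all-zero", {
  spec <- phantomSpec(imageSize = 32, nVessels = 0, noiseSigma = 0,
                      backgroundLevel = 0, seed = 1)
  s <- generatePhantom(spec)
  expect_true(all(sampleImage(s) == 0))
  expect_true(all(sampleMask(s) == 0))
})

test_that("invalid phantom specs raise parameter errors naming the bound", {
  expect_error(phantomSpec(imageSize = 16), class = "ts_parameter_error",
               regexp = "imageSize")
  expect_error(phantomSpec(vesselRadiusRange = c(10, 40)),
               class = "ts_parameter_error", regexp = "vesselRadiusRange")
  expect_error(phantomSpec(clotFraction = 0),
               class = "ts_parameter_error", regexp = "clotFraction")
  expect_error(generateDataset(phantomSpec(), 0),
               class = "ts_parameter_error")
})

test_that("datasets have the requested cardinality and are reproducible", {
  spec <- phantomSpec(imageSize = 32, vesselRadiusRange = c(4, 8))
  d1 <- generateDataset(spec, 10, seed = 7)
  d2 <- generateDataset(spec, 10, seed = 7)
  expect_length(d1, 10)
  for (i in seq_len(10)) {
    expect_identical(dim(sampleImage(d1[[i]])), c(32L, 32L))
    expect_identical(sampleImage(d1[[i]]), sampleImage(d2[[i]]))
    expect_identical(sampleMask(d1[[i]]), sampleMask(d2[[i]]))
  }
  seeds <- vapply(d1, function(s) sampleMeta(s)$seed, 1L)
  expect_length(unique(seeds), 10)
})

test_that("mean foreground fraction tracks the analytic expectation", {
  # one vessel, semi-axes ~ U(6, 14): E[clot area] = clotFraction * pi *
  # E[a] * E[b] = 0.5 * pi * 100 px^2 on a 64^2 grid
  spec <- phantomSpec(imageSize = 64, nVessels = 1,
                      vesselRadiusRange = c(6, 14), clotFraction = 0.5,
                      noiseSigma = 0)
  d <- generateDataset(spec, 200, seed = 123)
  frac <- mean(vapply(d, function(s) mean(sampleMask(s)), 1))
  expected <- 0.5 * pi * 10 * 10 / 64^2
  expect_gt(frac, expected * 0.8)
  expect_lt(frac, expected * 1.2)
})

test_that("confusion fixtures reproduce their counts exactly", {
  f <- generateConfusionFixture(10, 80, 5, 5, seed = 3)
  expect_identical(unname(brute_confusion(f$truth, f$pred)),
                   c(10L, 80L, 5L, 5L))
  # all-correct, all-negative
  f2 <- generateConfusionFixture(0, 36, 0, 0)
  expect_identical(unname(brute_confusion(f2$truth, f2$pred)),
                   c(0L, 36L, 0L, 0L))
  expect_equal(computeMetrics(confusionCounts(f2$truth, f2$pred))@accuracy, 1)
  # every pixel a false positive
  f3 <- generateConfusionFixture(0, 0, 25, 0)
  expect_identical(unname(brute_confusion(f3$truth, f3$pred)),
                   c(0L, 0L, 25L, 0L))
  expect_equal(computeMetrics(confusionCounts(f3$truth, f3$pred))@precision, 0)
  # prime totals fall back to a 1-row layout
  f4 <- generateConfusionFixture(3, 2, 1, 1, seed = 1)
  expect_identical(sort(dim(f4$truth)), c(1L, 7L))
  expect_error(generateConfusionFixture(0, 0, 0, 0),
               class = "ts_parameter_error")
})

test_that("masks are never altered by noise", {
  base <- phantomSpec(imageSize = 48, nVessels = 2,
                      vesselRadiusRange = c(5, 10), noiseSigma = 0,
                      seed = 9)
  noisy <- base
  noisy@noiseSigma <- 0.1
  expect_identical(sampleMask(generatePhantom(base)),
                   sampleMask(generatePhantom(noisy)))
})
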