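test_that("adaptive equalization honours its degenerate and ordering contracts", {
  cfg <- preprocessConfig(targetSize = 64)
  const <- matrix(0.37, 40, 40)
  expect_identical(equalizeAdaptive(const, cfg), const)
  # two-valued image: every high-pixel output >= every low-pixel output
  set.seed(1)
  two <- matrix(sample(c(0.2, 0.8), 64 * 64, replace = TRUE), 64, 64)
  out <- equalizeAdaptive(two, cfg)
  expect_gte(min(out[two == 0.8]), max(out[two == 0.2]))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(equalizeAdaptive(array(0, c(4, 4, 2)), cfg),
               class = "ts_shape_error")
})

test_that("equalization with a large clip limit flattens a skewed histogram", {
  cfg <- preprocessConfig(claheClipLimit = 1, targetSize = 64)
  ramp <- matrix(seq(0, 1, length.out = 64 * 64)^3, 64, 64)
  out <- equalizeAdaptive(ramp, cfg)
  sup_dist <- function(v) {
    s <- sort(as.vector(v))
    max(abs(seq_along(s) / length(s) - s))
  }
  expect_lt(sup_dist(out), sup_dist(ramp))
})

test_that("median denoising matches a brute-force sliding window", {
  cfg <- preprocessConfig(denoiseKernel = 3, targetSize = 64)
  expect_identical(denoiseImage(matrix(1:20 / 20, 4, 5),
                                preprocessConfig(denoiseKernel = 1,
                                                 targetSize = 64)),
                   matrix(1:20 / 20, 4, 5))
  # single impulse in a flat field is removed
  flat <- matrix(0.5, 9, 9)
  flat[5, 5] <- 1
  expect_true(all(denoiseImage(flat, cfg) == 0.5))
  set.seed(7)
  x <- matrix(runif(15 * 12), 15, 12)
  expect_equal(denoiseImage(x, cfg), brute_median(x, 3), tolerance = 1e-15)
  bad <- preprocessConfig(targetSize = 64)
  bad@denoiseKernel <- 4L
  expect_error(denoiseImage(x, bad), class = "ts_parameter_error")
})

test_that("intensity normalization maps linearly with stated conventions", {
  cfg <- preprocessConfig(targetSize = 64)
  x <- matrix(c(10, 15, 20, 12), 2, 2)
  out <- normalizeIntensity(x, cfg)
  expect_equal(out[2, 1], 0.5)  # value 15 of range [10, 20]
  expect_equal(min(out), 0, tolerance = 1e-12)
  expect_equal(max(out), 1, tolerance = 1e-12)
  const <- matrix(3, 4, 4)
  expect_true(all(normalizeIntensity(const, cfg) == 0.5))
  cfg2 <- preprocessConfig(normalizeRange = c(-1, 1), targetSize = 64)
  out2 <- normalizeIntensity(x, cfg2)
  expect_equal(range(out2), c(-1, 1), tolerance = 1e-12)
})

test_that("resizing obeys identity, binary and subsampling contracts", {
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(resizeImage(x, 64), x)
  # checkerboard downscaled 2x with nearest-neighbour: index arithmetic
  cb <- outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  small <- resizeImage(cb, 16, method = "nearest")
  expect_identical(small, cb[seq(1, 32, by = 2), seq(1, 32, by = 2)])
  # binary mask upscaled with nearest-neighbour stays binary
  m <- matrix(rbinom(16 * 16, 1, 0.4), 16, 16)
  up <- resizeImage(m + 0, 48, method = "nearest")
  expect_true(all(up %in% c(0, 1)))
})

test_that("the preprocessing pipeline preserves mask geometry and bounds", {
  spec <- phantomSpec(imageSize = 64, nVessels = 1, noiseSigma = 0, seed = 2)
  s <- generatePhantom(spec)
  cfg <- preprocessConfig(targetSize = 64)
  out <- suppressMessages(preprocessSample(s, cfg))
  # mask path touches geometry only: same size leaves the mask untouched
  expect_identical(sampleMask(out), sampleMask(s))
  img <- sampleImage(out)
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(dim(img), dim(sampleMask(out)))
  # downscale keeps the pair aligned and the mask binary
  cfg2 <- preprocessConfig(targetSize = 32)
  out2 <- suppressMessages(preprocessSample(s, cfg2))
  expect_identical(dim(sampleImage(out2)), c(32L, 32L))
  expect_true(all(sampleMask(out2) %in% c(0L, 1L)))
})

test_that("the pipeline is the identity on a normalized constant image", {
  s <- new("LabeledSample", image = matrix(0.5, 64, 64),
           mask = matrix(0L, 64, 64), meta = list())
  out <- preprocessSample(s, preprocessConfig(targetSize = 64))
  expect_identical(sampleImage(out), sampleImage(s))
  expect_identical(sampleMask(out), sampleMask(s))
})
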