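set_zero <- function(params, names) {
  for (nm in names) params@weights[[nm]]$value[] <- 0
  params
}

test_that("a zero-weight residual block is the identity in inference mode", {
  set.seed(1)
  p <- newBlockParams("residual", 4, 4)
  p <- set_zero(p, c("w1", "w2"))
  x <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  expect_equal(residualBlock(x, p), x, tolerance = 1e-12)
})

test_that("residual scalar case reduces to x + relu(w x)", {
  set.seed(2)
  p <- newBlockParams("residual", 1, 1, normalize = FALSE)
  p@weights$w1$value[] <- 0.7
  p@weights$w2$value[] <- 1
  x <- matrix(2, 1, 1)
  expect_equal(residualBlock(x, p), matrix(2 + 0.7 * 2, 1, 1),
               tolerance = 1e-12)
  p@weights$w1$value[] <- -0.7  # negative pre-activation: relu kills it
  expect_equal(residualBlock(x, p), x, tolerance = 1e-12)
})

test_that("residual blocks preserve spatial shape and project channels", {
  set.seed(3)
  p <- newBlockParams("residual", 3, 8)
  x <- array(rnorm(7 * 9 * 3), c(7, 9, 3))
  out <- residualBlock(x, p)
  expect_identical(dim(out), c(7L, 9L, 8L))
  expect_error(residualBlock(array(0, c(4, 4, 5)), p),
               class = "ts_config_error")
})

test_that("inception blocks concatenate three convs and a pooled copy", {
  set.seed(4)
  cin <- 3L
  f <- 5L
  p <- newBlockParams("inception", cin, f)
  x <- array(rnorm(8 * 8 * cin), c(8, 8, cin))
  out <- inceptionBlock(x, p)
  expect_identical(dim(out), c(8L, 8L, 3L * f + cin))
  # zero conv weights: first 3F channels zero, rest relu(maxpool3(x))
  pz <- set_zero(p, c("w1", "w3", "w5"))
  outz <- inceptionBlock(x, pz)
  expect_true(all(outz[, , seq_len(3 * f)] == 0))
  for (c in seq_len(cin))
    expect_equal(outz[, , 3 * f + c], pmax(brute_maxpool3(x[, , c]), 0),
                 tolerance = 1e-12)
  # ReLU on the concatenation keeps non-negative inputs non-negative
  expect_true(all(inceptionBlock(abs(x), p) >= 0))
})

test_that("dilated convolution widens the receptive field as K+(K-1)(D-1)", {
  expect_equal(receptiveField(3, 2), 5)
  expect_equal(receptiveField(3, 1), 3)
  expect_equal(receptiveField(5, 3), 13)
  set.seed(5)
  # D = 1 equals a plain convolution with shared weights
  p1 <- newBlockParams("dilated", 1, 1, kernelSize = 3, dilation = 1)
  kern <- matrix(rnorm(9), 3, 3)
  p1@weights$w$value[, , 1, 1] <- kern
  x <- matrix(rnorm(10 * 10), 10, 10)
  expect_equal(dilatedConvBlock(x, p1), brute_conv2d(x, kern, 1),
               tolerance = 1e-6)
  # impulse response of D = 2: taps only at offsets that are multiples of 2
  p2 <- newBlockParams("dilated", 1, 1, kernelSize = 3, dilation = 2)
  p2@weights$w$value[, , 1, 1] <- kern
  imp <- matrix(0, 11, 11)
  imp[6, 6] <- 1
  out <- dilatedConvBlock(imp, p2)
  nz <- which(out != 0, arr.ind = TRUE)
  offs <- cbind(nz[, 1] - 6, nz[, 2] - 6)
  expect_true(all(offs %% 2 == 0))
  expect_true(all(abs(offs) <= 2))
  expect_equal(out, brute_conv2d(imp, kern, 2), tolerance = 1e-12)
  expect_error(newBlockParams("dilated", 1, 1, dilation = 0),
               class = "ts_parameter_error")
})

test_that("spatial pyramid pooling tiles global statistics over the grid", {
  set.seed(6)
  cin <- 3L
  p <- newBlockParams("spp", cin, 4L)
  x <- array(rnorm(6 * 7 * cin), c(6, 7, cin))
  out <- spatialPyramidPool(x, p)
  expect_identical(dim(out), c(6L, 7L, 2L * cin + 4L))
  for (c in seq_len(cin)) {
    expect_true(all(out[, , c] == max(max(x[, , c]), 0)))
    expect_true(all(abs(out[, , cin + c] -
                          max(mean(x[, , c]), 0)) < 1e-12))
  }
  # constant input with zero conv weights: branches are (c, c, 0)
  pz <- p
  pz@weights$w$value[] <- 0
  pz@weights$b$value[] <- 0
  xc <- array(0.4, c(5, 5, cin))
  outc <- spatialPyramidPool(xc, pz)
  expect_true(all(outc[, , seq_len(2 * cin)] == 0.4))
  expect_true(all(outc[, , 2 * cin + seq_len(4)] == 0))
})

test_that("the attention gate attenuates with a sigmoid mask in (0, 1)", {
  set.seed(7)
  cin <- 4L
  p <- newBlockParams("attention", cin, cin)
  x <- array(abs(rnorm(8 * 8 * cin)), c(8, 8, cin))
  g <- array(rnorm(8 * 8 * cin), c(8, 8, cin))
  out <- attentionBlock(x, g, p)
  expect_identical(dim(out), dim(x))
  expect_true(all(out >= 0 & out <= x))  # mask strictly inside (0, 1)
  expect_true(all(out > 0 | x == 0))
  # zero mask conv: sigmoid(0) = 0.5 everywhere
  pz <- p
  pz@weights$w$value[] <- 0
  expect_equal(attentionBlock(x, g, pz), 0.5 * x, tolerance = 1e-12)
  # scalar hand case: x = g = 1, w = 1, b = 0
  p1 <- newBlockParams("attention", 1, 1)
  p1@weights$w$value[] <- 1
  p1@weights$b$value[] <- 0
  expect_equal(attentionBlock(matrix(1, 1, 1), matrix(1, 1, 1), p1)[1, 1],
               1 / (1 + exp(-2)), tolerance = 1e-10)
  expect_error(attentionBlock(x, array(0, c(4, 4, cin)), p),
               class = "ts_shape_error")
})

test_that("all blocks are deterministic in inference mode", {
  set.seed(8)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  pr <- newBlockParams("residual", 3, 3, dropoutRate = 0.5)
  expect_identical(residualBlock(x, pr), residualBlock(x, pr))
  pi_ <- newBlockParams("inception", 3, 2)
  expect_identical(inceptionBlock(x, pi_), inceptionBlock(x, pi_))
})

test_that("gradients flow through every block parameter", {
  set.seed(9)
  ad_param <- thromboseg:::ad_param
  x <- ad_param(array(rnorm(8 * 8 * 2), c(8, 8, 2, 1)))
  blocks <- list(
    incep = newBlockParams("inception", 2, 2),
    resid = newBlockParams("residual", 8, 4, dropoutRate = 0.1),
    dil = newBlockParams("dilated", 4, 4, dilation = 2),
    spp = newBlockParams("spp", 4, 4),
    att = newBlockParams("attention", 12, 12))
  ctx <- list(dropout = TRUE, bnTrain = TRUE, momentum = 0.1)
  h <- thromboseg:::.inception_fwd(x, blocks$incep, ctx)
  h <- thromboseg:::.residual_fwd(h, blocks$resid, ctx)
  h <- thromboseg:::.dilated_fwd(h, blocks$dil)
  h <- thromboseg:::.spp_fwd(h, blocks$spp, ctx)
  h <- thromboseg:::.attention_fwd(h, thromboseg:::ad_const(h$value),
                                   blocks$att)
  loss <- thromboseg:::ad_bce(thromboseg:::ad_sigmoid(h),
                              array(0, dim(h$value)))
  thromboseg:::ad_backward(loss)
  for (b in blocks) {
    for (nm in names(b@weights)) {
      g <- b@weights[[nm]]$grad
      expect_false(is.null(g), info = nm)
      expect_true(all(is.finite(g)), info = nm)
    }
  }
  expect_true(all(is.finite(x$grad)))
})
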