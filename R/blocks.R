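#' Block parameters
#'
#' Configuration and learnable parameter store for one architectural block.
#' Weights are created by [newBlockParams()] with He-initialized convolution
#' kernels (draws come from the session RNG, so seed before building for
#' reproducibility), zero biases, and identity batch-norm affines; they live
#' in autodiff parameter nodes, so a block embedded in a model is updated in
#' place by the optimizer.
#'
#' @slot type one of "residual", "inception", "dilated", "spp", "attention".
#' @slot inputChannels channel count the weights were built for.
#' @slot filters filter count F.
#' @slot kernelSize odd kernel width K.
#' @slot dilation dilation rate D (>= 1; used by the dilated block).
#' @slot dropoutRate dropout fraction in \[0, 1).
#' @slot normalize logical; `FALSE` bypasses batch normalization (a testing
#'   hook for hand-arithmetic checks).
#' @slot maskChannels "single" (one spatial attention mask broadcast over
#'   channels, the default) or "per-channel".
#' @slot weights named list of autodiff parameter nodes.
#' @slot norm named list of running-statistics environments.
#' @seealso [residualBlock()], [inceptionBlock()], [dilatedConvBlock()],
#'   [spatialPyramidPool()], [attentionBlock()]
#' @export
setClass("BlockParams", representation(
  type = "character", inputChannels = "integer", filters = "integer",
  kernelSize = "integer", dilation = "integer", dropoutRate = "numeric",
  normalize = "logical", maskChannels = "character",
  weights = "list", norm = "list"
))

.he_kernel <- function(kh, kw, cin, f) {
  array(rnorm(kh * kw * cin * f, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, f))
}

.bn_state <- function(f) {
  e <- new.env(parent = emptyenv())
  e$mean <- rep(0, f)
  e$var <- rep(1, f)
  e
}

#' Create block parameters
#'
#' @param type block type: "residual", "inception", "dilated", "spp" or
#'   "attention".
#' @param inputChannels channels of the feature map the block will receive.
#' @param filters filter count F.
#' @param kernelSize odd kernel width (residual and dilated blocks).
#' @param dilation dilation rate (dilated block; must be >= 1).
#' @param dropoutRate dropout fraction in \[0, 1) (residual block).
#' @param normalize apply batch normalization (residual block).
#' @param maskChannels "single" or "per-channel" (attention block).
#' @return A [BlockParams-class] with freshly initialized weights.
#' @export
newBlockParams <- function(type, inputChannels, filters,
                           kernelSize = 3L, dilation = 1L,
                           dropoutRate = 0, normalize = TRUE,
                           maskChannels = c("single", "per-channel")) {
  type <- match.arg(type,
    c("residual", "inception", "dilated", "spp", "attention"))
  maskChannels <- match.arg(maskChannels)
  cin <- as.integer(inputChannels)
  f <- as.integer(filters)
  k <- as.integer(kernelSize)
  d <- as.integer(dilation)
  if (cin < 1L || f < 1L) stop_param("channel and filter counts must be >= 1")
  if (k < 1L || k %% 2L == 0L) stop_param("kernelSize must be odd")
  if (d < 1L) stop_param("dilation rate must be >= 1")
  if (dropoutRate < 0 || dropoutRate >= 1)
    stop_param("dropoutRate must be in [0, 1)")
  w <- list()
  nrm <- list()
  if (type == "residual") {
    w$w1 <- ad_param(.he_kernel(k, k, cin, f)); w$b1 <- ad_param(rep(0, f))
    w$g1 <- ad_param(rep(1, f)); w$be1 <- ad_param(rep(0, f))
    w$w2 <- ad_param(.he_kernel(k, k, f, f)); w$b2 <- ad_param(rep(0, f))
    w$g2 <- ad_param(rep(1, f)); w$be2 <- ad_param(rep(0, f))
    if (cin != f) {
      w$wp <- ad_param(.he_kernel(1L, 1L, cin, f))
      w$bp <- ad_param(rep(0, f))
    }
    nrm$rs1 <- .bn_state(f)
    nrm$rs2 <- .bn_state(f)
  } else if (type == "inception") {
    w$w1 <- ad_param(.he_kernel(1L, 1L, cin, f)); w$b1 <- ad_param(rep(0, f))
    w$w3 <- ad_param(.he_kernel(3L, 3L, cin, f)); w$b3 <- ad_param(rep(0, f))
    w$w5 <- ad_param(.he_kernel(5L, 5L, cin, f)); w$b5 <- ad_param(rep(0, f))
  } else if (type == "dilated") {
    w$w <- ad_param(.he_kernel(k, k, cin, f)); w$b <- ad_param(rep(0, f))
  } else if (type == "spp") {
    w$w <- ad_param(.he_kernel(1L, 1L, cin, f)); w$b <- ad_param(rep(0, f))
  } else {
    fm <- if (maskChannels == "single") 1L else cin
    w$w <- ad_param(.he_kernel(1L, 1L, cin, fm)); w$b <- ad_param(rep(0, fm))
  }
  new("BlockParams", type = type, inputChannels = cin, filters = f,
      kernelSize = k, dilation = d, dropoutRate = as.numeric(dropoutRate),
      normalize = as.logical(normalize), maskChannels = maskChannels,
      weights = w, norm = nrm)
}

#' @describeIn BlockParams-class output channel count for a given block
#' @param params a `BlockParams`
#' @export
blockOutputChannels <- function(params) {
  switch(params@type,
    residual = params@filters,
    inception = 3L * params@filters + params@inputChannels,
    dilated = params@filters,
    spp = 2L * params@inputChannels + params@filters,
    attention = params@inputChannels)
}

setMethod("show", "BlockParams", function(object) {
  cat(sprintf("BlockParams<%s>: %d -> %d channels, K=%d, D=%d\n",
              object@type, object@inputChannels,
              blockOutputChannels(object), object@kernelSize,
              object@dilation))
})

# Accept a feature map as an (H, W, C) array, an (H, W) matrix (C = 1), a
# 4-D (H, W, C, N) batch, or an autodiff node; return a node plus enough
# information to hand the result back in the caller's form.
.fm_in <- function(x, params = NULL, what = "x") {
  if (is_node(x)) {
    v <- x$value
    form <- "node"
  } else {
    v <- x
    if (is.matrix(v)) {
      dim(v) <- c(dim(v), 1L, 1L)
      form <- "matrix"
    } else if (length(dim(v)) == 3L) {
      dim(v) <- c(dim(v), 1L)
      form <- "array3"
    } else if (length(dim(v)) == 4L) {
      form <- "array4"
    } else {
      stop_shape(sprintf("%s must be an (H, W, C) feature map", what))
    }
    if (any(!is.finite(v)))
      stop_shape(sprintf("%s must be finite-valued", what))
  }
  if (any(dim(v)[1:3] < 1L))
    stop_shape(sprintf("%s must have positive extents", what))
  if (!is.null(params) && dim(v)[3] != params@inputChannels)
    stop_config(sprintf(
      "%s has %d channels but the block was built for %d",
      what, dim(v)[3], params@inputChannels))
  node <- if (is_node(x)) x else ad_const(v)
  list(node = node, form = form)
}

.fm_out <- function(node, form) {
  if (form == "node") return(node)
  v <- node$value
  if (form == "matrix" && dim(v)[3] == 1L) {
    dim(v) <- dim(v)[1:2]
  } else if (form != "array4") {
    dim(v) <- dim(v)[1:3]
  }
  v
}

.check_type <- function(params, type) {
  if (!is(params, "BlockParams") || params@type != type)
    stop_param(sprintf("params must be BlockParams of type '%s'", type))
}

# Forward context: dropout on/off, batch-norm statistics source, and the
# running-statistics update momentum. "train" = dropout + batch stats,
# "eval" = neither, "calibrate" = batch stats with dropout off (used to
# re-estimate running statistics, see .calibrateNorm).
.fwd_ctx <- function(training) {
  list(dropout = isTRUE(training), bnTrain = isTRUE(training),
       momentum = 0.1)
}

.residual_fwd <- function(xn, p, ctx) {
  w <- p@weights
  h <- ad_conv2d(xn, w$w1, w$b1)
  h <- ad_dropout(h, p@dropoutRate, ctx$dropout)
  if (p@normalize)
    h <- ad_batchnorm(h, w$g1, w$be1, p@norm$rs1, ctx$bnTrain,
                      momentum = ctx$momentum)
  h <- ad_relu(h)
  h <- ad_conv2d(h, w$w2, w$b2)
  h <- ad_dropout(h, p@dropoutRate, ctx$dropout)
  if (p@normalize)
    h <- ad_batchnorm(h, w$g2, w$be2, p@norm$rs2, ctx$bnTrain,
                      momentum = ctx$momentum)
  h <- ad_relu(h)
  sc <- if (!is.null(w$wp)) ad_conv2d(xn, w$wp, w$bp) else xn
  ad_add(sc, h)
}

#' Residual block
#'
#' Two convolutional sublayers, each ordered conv -> dropout -> batch
#' normalization -> ReLU, with the block input added to the second
#' sublayer's output through a skip connection. When the input channel
#' count differs from `filters`, a 1x1 projection is applied on the skip
#' path (the addition is otherwise undefined). Spatial shape is preserved
#' (same padding); output channels equal `filters`.
#'
#' @param x feature map: (H, W, C) array, (H, W) matrix, or (H, W, C, N)
#'   batch.
#' @param params a [BlockParams-class] of type "residual".
#' @param training logical; enables dropout and batch-statistics
#'   normalization.
#' @return feature map of shape (H, W, filters).
#' @export
residualBlock <- function(x, params, training = FALSE) {
  .check_type(params, "residual")
  xi <- .fm_in(x, params)
  .fm_out(.residual_fwd(xi$node, params, .fwd_ctx(training)), xi$form)
}

.inception_fwd <- function(xn, p, ctx = NULL) {
  w <- p@weights
  b1 <- ad_conv2d(xn, w$w1, w$b1)
  b3 <- ad_conv2d(xn, w$w3, w$b3)
  b5 <- ad_conv2d(xn, w$w5, w$b5)
  mp <- ad_maxpool3_same(xn)
  ad_relu(ad_concat(list(b1, b3, b5, mp)))
}

#' Inception block
#'
#' Four parallel branches over the input: 1x1, 3x3 and 5x5 convolutions
#' (each with `filters` filters, same padding) and a 3x3 stride-1 max-pool,
#' concatenated along channels with ReLU applied to the concatenation.
#' Output channels: `3 * filters + C_in`.
#'
#' @inheritParams residualBlock
#' @param params a [BlockParams-class] of type "inception".
#' @export
inceptionBlock <- function(x, params, training = FALSE) {
  .check_type(params, "inception")
  xi <- .fm_in(x, params)
  .fm_out(.inception_fwd(xi$node, params, .fwd_ctx(training)), xi$form)
}

.dilated_fwd <- function(xn, p) {
  ad_conv2d(xn, p@weights$w, p@weights$b, dilation = p@dilation)
}

#' Dilated convolution block
#'
#' A single same-padded convolution whose kernel taps are spaced by the
#' dilation rate D, enlarging the receptive field to
#' `K + (K - 1) (D - 1)` per axis without downsampling. With D = 1 this is
#' an ordinary convolution.
#'
#' @inheritParams residualBlock
#' @param params a [BlockParams-class] of type "dilated".
#' @export
dilatedConvBlock <- function(x, params, training = FALSE) {
  .check_type(params, "dilated")
  xi <- .fm_in(x, params)
  .fm_out(.dilated_fwd(xi$node, params), xi$form)
}

#' @describeIn dilatedConvBlock effective receptive field per axis
#' @param kernelSize odd kernel width K.
#' @param dilation dilation rate D.
#' @export
receptiveField <- function(kernelSize, dilation)
  kernelSize + (kernelSize - 1) * (dilation - 1)

.spp_fwd <- function(xn, p, ctx = NULL) {
  gmax <- ad_gmaxpool_tile(xn)
  gavg <- ad_gavgpool_tile(xn)
  cavg <- ad_gavgpool_tile(ad_conv2d(xn, p@weights$w, p@weights$b))
  ad_relu(ad_concat(list(gmax, gavg, cavg)))
}

#' Spatial pyramid pooling block
#'
#' Three branches reduce the input to per-channel scalars -- global max
#' pooling, global average pooling, and global average pooling of a 1x1
#' convolution -- which are tiled back to the (H, W) grid and concatenated
#' along channels with ReLU, injecting image-level context while keeping
#' the spatial pipeline intact. Output channels: `2 * C_in + filters`.
#'
#' @inheritParams residualBlock
#' @param params a [BlockParams-class] of type "spp".
#' @export
spatialPyramidPool <- function(x, params, training = FALSE) {
  .check_type(params, "spp")
  xi <- .fm_in(x, params)
  .fm_out(.spp_fwd(xi$node, params, .fwd_ctx(training)), xi$form)
}

.attention_fwd <- function(xn, gn, p) {
  f <- ad_relu(ad_add(xn, gn))
  mask <- ad_sigmoid(ad_conv2d(f, p@weights$w, p@weights$b))
  ad_mul_mask(xn, mask)
}

#' Attention gate block
#'
#' Computes `F = relu(x + g)` from the input and a gating signal already
#' projected/resampled to the input's shape, derives a sigmoid attention
#' mask `F' = sigmoid(conv1x1(F))` with values strictly in (0, 1), and
#' returns the elementwise product `x * F'`. By default the mask has a
#' single channel broadcast across the input channels
#' (`maskChannels = "per-channel"` gives one mask per channel).
#'
#' @inheritParams residualBlock
#' @param g gating signal with exactly the input's shape.
#' @param params a [BlockParams-class] of type "attention".
#' @export
attentionBlock <- function(x, g, params, training = FALSE) {
  .check_type(params, "attention")
  xi <- .fm_in(x, params)
  gi <- .fm_in(g, params, what = "g")
  if (!identical(dim(xi$node$value), dim(gi$node$value)))
    stop_shape("gating signal must be projected/resampled to x's shape")
  .fm_out(.attention_fwd(xi$node, gi$node, params), xi$form)
}

# All parameter nodes of a block, named.
.block_params <- function(p, prefix) {
  setNames(p@weights, paste(prefix, names(p@weights), sep = "."))
}
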