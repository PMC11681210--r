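#' Model configuration
#'
#' Architecture hyperparameters of the segmentation network. The published
#' description leaves depth and filter widths unstated; the defaults here
#' (depth 4, 32 base filters, doubling per level) are standard
#' encoder-decoder sizing and every value is configurable.
#'
#' @slot depth encoder levels (>= 1).
#' @slot baseFilters filters at the first level.
#' @slot filterGrowth per-level filter multiplier.
#' @slot inputSize input pixels per side; must be divisible by 2^depth.
#' @slot dropoutRate dropout fraction used inside residual blocks and after
#'   each encoder downsample.
#' @slot dilationRate dilation of the bottleneck dilated convolution
#'   (default 2).
#' @slot threshold probability cutoff for the binary mask, in (0, 1).
#' @export
setClass("ModelConfig", representation(
  depth = "integer", baseFilters = "integer", filterGrowth = "numeric",
  inputSize = "integer", dropoutRate = "numeric", dilationRate = "integer",
  threshold = "numeric"
))

setValidity("ModelConfig", function(object) {
  msg <- character(0)
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (object@baseFilters < 1L) msg <- c(msg, "baseFilters must be >= 1")
  if (object@filterGrowth <= 0) msg <- c(msg, "filterGrowth must be > 0")
  if (object@inputSize < 2L^object@depth ||
      object@inputSize %% 2L^object@depth != 0L)
    msg <- c(msg, "inputSize must be divisible by 2^depth")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (object@dilationRate < 1L) msg <- c(msg, "dilationRate must be >= 1")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Create a model configuration
#'
#' @param depth encoder levels.
#' @param baseFilters filters at the first encoder level.
#' @param filterGrowth per-level filter multiplier.
#' @param inputSize input pixels per side (divisible by 2^depth).
#' @param dropoutRate dropout fraction.
#' @param dilationRate bottleneck dilation rate.
#' @param threshold probability cutoff in (0, 1).
#' @return A [ModelConfig-class].
#' @export
modelConfig <- function(depth = 4L, baseFilters = 32L, filterGrowth = 2,
                        inputSize = 256L, dropoutRate = 0.25,
                        dilationRate = 2L, threshold = 0.5) {
  obj <- tryCatch(new("ModelConfig", depth = as.integer(depth),
             baseFilters = as.integer(baseFilters),
             filterGrowth = as.numeric(filterGrowth),
             inputSize = as.integer(inputSize),
             dropoutRate = as.numeric(dropoutRate),
             dilationRate = as.integer(dilationRate),
             threshold = as.numeric(threshold)),
    error = function(e) stop_config(conditionMessage(e)))
  obj
}

.config_to_list <- function(cfg) {
  list(depth = cfg@depth, baseFilters = cfg@baseFilters,
       filterGrowth = cfg@filterGrowth, inputSize = cfg@inputSize,
       dropoutRate = cfg@dropoutRate, dilationRate = cfg@dilationRate,
       threshold = cfg@threshold)
}

.config_from_list <- function(x) {
  do.call(modelConfig, x)
}

#' Segmentation network
#'
#' An encoder-decoder network for binary segmentation. Per encoder level:
#' inception block, residual block (the pre-pool output feeds the decoder
#' skip), 2x2 max-pool downsample, dropout, batch normalization. At the
#' bottleneck: an inception block whose output, projected by a 1x1
#' convolution, gates the encoder output through an attention block; then a
#' dilated convolution (rate 2) and spatial pyramid pooling. Per decoder
#' level: 2x2 transpose-convolution upsample, channel concatenation with
#' the matching encoder skip, inception and residual blocks. A final 1x1
#' convolution with sigmoid yields the per-pixel foreground probability
#' map.
#'
#' @slot config the [ModelConfig-class].
#' @slot layers nested list of block parameters.
#' @slot params flat named list of all parameter nodes.
#' @slot state flat named list of batch-norm running-statistics
#'   environments.
#' @seealso [thrombusNet()], [predictProbability()], [trainModel()]
#' @export
setClass("ThrombusNet", representation(
  config = "ModelConfig", layers = "list", params = "list", state = "list"
))

#' Build the segmentation network
#'
#' @param config a [ModelConfig-class].
#' @param seed optional seed for weight initialization; when `NULL` the
#'   session RNG is used as-is.
#' @return A [ThrombusNet-class] with freshly initialized weights.
#' @examples
#' net <- thrombusNet(modelConfig(depth = 2, baseFilters = 8,
#'                                inputSize = 64), seed = 1)
#' countParameters(net)
#' @export
thrombusNet <- function(config = modelConfig(), seed = NULL) {
  v <- validObject(config, test = TRUE)
  if (!isTRUE(v)) stop_config(paste(v, collapse = "; "))
  build <- function() .build_net(config)
  if (is.null(seed)) build() else with_seed(seed, build())
}

.build_net <- function(cfg) {
  fl <- function(l) max(1L, as.integer(round(cfg@baseFilters *
                                               cfg@filterGrowth^(l - 1))))
  enc <- list()
  cin <- 1L
  for (l in seq_len(cfg@depth)) {
    f <- fl(l)
    incep <- newBlockParams("inception", cin, f)
    resid <- newBlockParams("residual", blockOutputChannels(incep), f,
                            dropoutRate = cfg@dropoutRate)
    enc[[l]] <- list(incep = incep, resid = resid,
                     bnGamma = ad_param(rep(1, f)),
                     bnBeta = ad_param(rep(0, f)),
                     bnState = .bn_state(f))
    cin <- f
  }
  fb <- fl(cfg@depth + 1L)
  incepB <- newBlockParams("inception", cin, fb)
  gateW <- ad_param(.he_kernel(1L, 1L, blockOutputChannels(incepB), cin))
  gateB <- ad_param(rep(0, cin))
  att <- newBlockParams("attention", cin, cin)
  dil <- newBlockParams("dilated", cin, fb, kernelSize = 3L,
                        dilation = cfg@dilationRate)
  spp <- newBlockParams("spp", fb, fb)
  bot <- list(incep = incepB, gateW = gateW, gateB = gateB, att = att,
              dilated = dil, spp = spp)
  ccur <- blockOutputChannels(spp)
  dec <- list()
  for (l in rev(seq_len(cfg@depth))) {
    f <- fl(l)
    upW <- ad_param(.he_kernel(2L, 2L, ccur, f))
    upB <- ad_param(rep(0, f))
    incep <- newBlockParams("inception", 2L * f, f)
    resid <- newBlockParams("residual", blockOutputChannels(incep), f,
                            dropoutRate = cfg@dropoutRate)
    dec[[l]] <- list(upW = upW, upB = upB, incep = incep, resid = resid)
    ccur <- f
  }
  head <- list(w = ad_param(.he_kernel(1L, 1L, fl(1L), 1L)),
               b = ad_param(rep(0, 1)))
  layers <- list(enc = enc, bot = bot, dec = dec, head = head)
  new("ThrombusNet", config = cfg, layers = layers,
      params = .collect_params(layers, cfg@depth),
      state = .collect_state(layers, cfg@depth))
}

.collect_params <- function(layers, depth) {
  out <- list()
  for (l in seq_len(depth)) {
    e <- layers$enc[[l]]
    out <- c(out, .block_params(e$incep, sprintf("enc%d.incep", l)),
             .block_params(e$resid, sprintf("enc%d.resid", l)),
             setNames(list(e$bnGamma, e$bnBeta),
                      sprintf("enc%d.bn.%s", l, c("gamma", "beta"))))
  }
  b <- layers$bot
  out <- c(out, .block_params(b$incep, "bot.incep"),
           list(bot.gateW = b$gateW, bot.gateB = b$gateB),
           .block_params(b$att, "bot.att"),
           .block_params(b$dilated, "bot.dilated"),
           .block_params(b$spp, "bot.spp"))
  for (l in seq_len(depth)) {
    d <- layers$dec[[l]]
    out <- c(out, setNames(list(d$upW, d$upB),
                           sprintf("dec%d.up.%s", l, c("w", "b"))),
             .block_params(d$incep, sprintf("dec%d.incep", l)),
             .block_params(d$resid, sprintf("dec%d.resid", l)))
  }
  c(out, list(head.w = layers$head$w, head.b = layers$head$b))
}

.collect_state <- function(layers, depth) {
  out <- list()
  for (l in seq_len(depth)) {
    e <- layers$enc[[l]]
    out[[sprintf("enc%d.resid.rs1", l)]] <- e$resid@norm$rs1
    out[[sprintf("enc%d.resid.rs2", l)]] <- e$resid@norm$rs2
    out[[sprintf("enc%d.bn", l)]] <- e$bnState
  }
  for (l in seq_len(depth)) {
    d <- layers$dec[[l]]
    out[[sprintf("dec%d.resid.rs1", l)]] <- d$resid@norm$rs1
    out[[sprintf("dec%d.resid.rs2", l)]] <- d$resid@norm$rs2
  }
  out
}

# Full forward pass on an (H, W, 1, N) batch node. Modes: "eval"
# (inference: no dropout, running statistics), "train" (dropout + batch
# statistics), "calibrate" (batch statistics with dropout off, used to
# re-estimate the running statistics after a training epoch).
.forward_net <- function(model, xn, mode = "eval", momentum = 0.1) {
  ctx <- switch(mode,
    train = list(dropout = TRUE, bnTrain = TRUE, momentum = momentum),
    eval = list(dropout = FALSE, bnTrain = FALSE, momentum = momentum),
    calibrate = list(dropout = FALSE, bnTrain = TRUE, momentum = momentum),
    stop_param(sprintf("unknown forward mode '%s'", mode)))
  cfg <- model@config
  ly <- model@layers
  skips <- vector("list", cfg@depth)
  h <- xn
  for (l in seq_len(cfg@depth)) {
    e <- ly$enc[[l]]
    h <- .inception_fwd(h, e$incep, ctx)
    h <- .residual_fwd(h, e$resid, ctx)
    skips[[l]] <- h
    h <- ad_maxpool2(h)
    h <- ad_dropout(h, cfg@dropoutRate, ctx$dropout)
    h <- ad_batchnorm(h, e$bnGamma, e$bnBeta, e$bnState, ctx$bnTrain,
                      momentum = ctx$momentum)
  }
  encOut <- h
  b <- ly$bot
  bi <- .inception_fwd(h, b$incep, ctx)
  g <- ad_conv2d(bi, b$gateW, b$gateB)
  h <- .attention_fwd(encOut, g, b$att)
  h <- .dilated_fwd(h, b$dilated)
  h <- .spp_fwd(h, b$spp, ctx)
  for (l in rev(seq_len(cfg@depth))) {
    d <- ly$dec[[l]]
    h <- ad_convt2(h, d$upW, d$upB)
    h <- ad_concat(list(h, skips[[l]]))
    h <- .inception_fwd(h, d$incep, ctx)
    h <- .residual_fwd(h, d$resid, ctx)
  }
  ad_sigmoid(ad_conv2d(h, ly$head$w, ly$head$b))
}

# Re-estimate batch-norm running statistics with dropout disabled. The
# block equations place dropout between each convolution and its batch
# normalization, so statistics accumulated during training describe
# dropout-inflated activations; inference would otherwise see a
# systematically different scale. Running up to `maxBatches` forward
# passes with momentum 1, 1/2, ..., 1/k leaves the running statistics at
# the exact average of the k dropout-free batch statistics.
.calibrateNorm <- function(model, x, batchSize, maxBatches = 4L) {
  n <- dim(x)[4]
  starts <- seq(1L, n, by = batchSize)
  starts <- starts[seq_len(min(maxBatches, length(starts)))]
  for (i in seq_along(starts)) {
    idx <- starts[i]:min(starts[i] + batchSize - 1L, n)
    invisible(.forward_net(model, ad_const(x[, , , idx, drop = FALSE]),
                           mode = "calibrate", momentum = 1 / i))
  }
  invisible(model)
}

#' Predict a per-pixel foreground probability map
#'
#' Runs the network in inference mode (dropout disabled, batch
#' normalization using running statistics), so repeated calls on the same
#' input are bit-identical, and batched and single-sample inference agree.
#'
#' @param model a [ThrombusNet-class].
#' @param image numeric matrix of side `inputSize` (already preprocessed),
#'   or an (H, W, N) array of such images.
#' @return matrix (or (H, W, N) array) of probabilities in \[0, 1\].
#' @export
predictProbability <- function(model, image) {
  if (!is(model, "ThrombusNet")) stop_param("model must be a ThrombusNet")
  sz <- model@config@inputSize
  batched <- length(dim(image)) == 3L
  v <- image
  if (is.matrix(v)) {
    dim(v) <- c(dim(v), 1L, 1L)
  } else if (batched) {
    dim(v) <- c(dim(v)[1:2], 1L, dim(v)[3])
  } else {
    stop_shape("image must be a matrix or an (H, W, N) array")
  }
  if (dim(v)[1] != sz || dim(v)[2] != sz)
    stop_shape(sprintf("image must be %dx%d (model input size)", sz, sz))
  out <- .forward_net(model, ad_const(v), mode = "eval")$value
  if (batched) {
    dim(out) <- c(sz, sz, dim(out)[4])
    out
  } else {
    matrix(out, sz, sz)
  }
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability is greater than or equal to
#' the cutoff (ties count as foreground), classifying each pixel as region
#' of interest or background. Raising the threshold can only remove
#' foreground pixels.
#'
#' @param p matrix of probabilities in \[0, 1\].
#' @param threshold cutoff strictly inside (0, 1).
#' @return integer matrix with values in \{0, 1\}.
#' @export
thresholdProbabilities <- function(p, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop_param("threshold must lie strictly inside (0, 1)")
  out <- (p >= threshold) + 0L
  storage.mode(out) <- "integer"
  out
}

#' Number of learnable parameters
#'
#' Counts every element of every convolution kernel, bias and batch-norm
#' affine in the model (running statistics are state, not parameters).
#'
#' @param model a [ThrombusNet-class].
#' @return integer count.
#' @export
countParameters <- function(model) {
  sum(vapply(model@params, function(p) length(p$value), 0))
}

setMethod("show", "ThrombusNet", function(object) {
  cfg <- object@config
  cat(sprintf(
    "ThrombusNet: depth %d, base filters %d (growth x%g), input %dx%d\n",
    cfg@depth, cfg@baseFilters, cfg@filterGrowth, cfg@inputSize,
    cfg@inputSize))
  cat(sprintf("  %d learnable parameters, dilation %d, threshold %.2f\n",
              countParameters(object), cfg@dilationRate, cfg@threshold))
})

#' Save a model checkpoint
#'
#' Writes the parameter arrays and batch-norm running statistics as an RDS
#' checkpoint, with a JSON sidecar (`<path>.json`) recording the
#' [ModelConfig-class] so the configuration round-trips exactly.
#'
#' @param model a [ThrombusNet-class].
#' @param path checkpoint file path (e.g. `model.rds`).
#' @return invisibly, `path`.
#' @export
saveModel <- function(model, path) {
  obj <- list(
    config = .config_to_list(model@config),
    weights = lapply(model@params, function(p) p$value),
    state = lapply(model@state, function(e) list(mean = e$mean,
                                                 var = e$var)))
  saveRDS(obj, path)
  jsonlite::write_json(obj$config, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [saveModel()].
#' @return A [ThrombusNet-class] with the saved weights and statistics.
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("checkpoint '%s' not found", path))
  obj <- readRDS(path)
  model <- thrombusNet(.config_from_list(obj$config), seed = 0L)
  for (nm in names(obj$weights)) {
    if (is.null(model@params[[nm]]))
      stop_valid(sprintf("checkpoint parameter '%s' unknown to this model",
                         nm))
    model@params[[nm]]$value <- obj$weights[[nm]]
  }
  for (nm in names(obj$state)) {
    model@state[[nm]]$mean <- obj$state[[nm]]$mean
    model@state[[nm]]$var <- obj$state[[nm]]$var
  }
  model
}
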