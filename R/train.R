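#' Training configuration
#'
#' The training protocol: random 80/10/10 split, Adam optimization of
#' binary cross-entropy at learning rate 0.001, batch size 16, up to 50
#' epochs with early stopping at a patience of 10 epochs on validation
#' loss, dropout 0.25. Adam moment parameters are the universal defaults
#' (beta1 0.9, beta2 0.999, eps 1e-8); there is no learning-rate schedule
#' and no augmentation.
#'
#' @slot splitFractions numeric(3) train/validation/test fractions, positive
#'   and summing to 1.
#' @slot learningRate Adam step size.
#' @slot epochs maximum epoch count.
#' @slot batchSize samples per optimization step.
#' @slot patience epochs without validation-loss improvement before
#'   stopping (<= epochs).
#' @slot dropoutRate dropout fraction.
#' @slot seed RNG seed governing the split, shuffles and dropout masks.
#' @export
setClass("TrainConfig", representation(
  splitFractions = "numeric", learningRate = "numeric", epochs = "integer",
  batchSize = "integer", patience = "integer", dropoutRate = "numeric",
  seed = "integer"
))

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  f <- object@splitFractions
  if (length(f) != 3L || any(f <= 0))
    msg <- c(msg, "splitFractions must be three positive fractions")
  if (length(f) == 3L && abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "splitFractions must sum to 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@patience < 1L || object@patience > object@epochs)
    msg <- c(msg, "patience must be in [1, epochs]")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Create a training configuration
#'
#' @param splitFractions train/validation/test fractions.
#' @param learningRate Adam step size.
#' @param epochs maximum epochs.
#' @param batchSize samples per step.
#' @param patience early-stopping patience in epochs.
#' @param dropoutRate dropout fraction.
#' @param seed RNG seed.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(splitFractions = c(0.8, 0.1, 0.1),
                        learningRate = 0.001, epochs = 50L,
                        batchSize = 16L, patience = 10L,
                        dropoutRate = 0.25, seed = 1L) {
  obj <- tryCatch(new("TrainConfig", splitFractions = as.numeric(splitFractions),
             learningRate = as.numeric(learningRate),
             epochs = as.integer(epochs), batchSize = as.integer(batchSize),
             patience = as.integer(patience),
             dropoutRate = as.numeric(dropoutRate), seed = as.integer(seed)),
    error = function(e) stop_param(conditionMessage(e)))
  obj
}

.trainconfig_to_list <- function(cfg) {
  list(splitFractions = cfg@splitFractions, learningRate = cfg@learningRate,
       epochs = cfg@epochs, batchSize = cfg@batchSize,
       patience = cfg@patience, dropoutRate = cfg@dropoutRate,
       seed = cfg@seed)
}

#' Training log
#'
#' Per-epoch record of training/validation loss and the six validation
#' ratio metrics, plus the best epoch (minimum validation loss over the
#' recorded epochs) and whether early stopping triggered.
#'
#' @slot history data frame with one row per completed epoch.
#' @slot bestEpoch epoch index whose weights the trained model carries.
#' @slot stoppedEarly logical.
#' @export
setClass("TrainLog", representation(
  history = "data.frame", bestEpoch = "integer", stoppedEarly = "logical"
))

setMethod("show", "TrainLog", function(object) {
  cat(sprintf("TrainLog: %d epoch(s), best epoch %d%s\n",
              nrow(object@history), object@bestEpoch,
              if (object@stoppedEarly) " (stopped early)" else ""))
  if (nrow(object@history))
    print(utils::tail(object@history[, c("epoch", "trainLoss", "valLoss",
                                         "valDice")], 3))
})

#' @describeIn TrainLog-class per-epoch history accessor
#' @param x a `TrainLog`
#' @export
trainHistory <- function(x) x@history

#' @describeIn TrainLog-class best (restored) epoch accessor
#' @export
bestEpoch <- function(x) x@bestEpoch

#' Random train/validation/test split
#'
#' Shuffles indices under the configured seed and cuts them into disjoint,
#' exhaustive index sets whose sizes are the fractions rounded to integers
#' by largest remainder, preserving the total (100 samples at 80/10/10
#' give exactly 80/10/10).
#'
#' @param samples list of samples, or a single integer count.
#' @param cfg a [TrainConfig-class].
#' @return list of sorted integer vectors `train`, `val`, `test`.
#' @export
splitDataset <- function(samples, cfg = trainConfig()) {
  n <- if (is.numeric(samples) && length(samples) == 1L)
    as.integer(samples) else length(samples)
  if (n < 10L) stop_valid("at least 10 samples are required to split")
  raw <- n * cfg@splitFractions
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  if (any(sizes < 1))
    stop_valid("each split must receive at least one sample")
  perm <- with_seed(cfg@seed, sample.int(n))
  bounds <- cumsum(sizes)
  list(train = sort(perm[seq_len(bounds[1])]),
       val = sort(perm[(bounds[1] + 1):bounds[2]]),
       test = sort(perm[(bounds[2] + 1):bounds[3]]))
}

# Stack LabeledSamples into (H, W, 1, N) image and (H, W, 1, N) mask arrays.
.stack_samples <- function(samples, idx, size) {
  n <- length(idx)
  x <- array(0, c(size, size, 1L, n))
  y <- array(0, c(size, size, 1L, n))
  for (i in seq_len(n)) {
    s <- samples[[idx[i]]]
    img <- sampleImage(s)
    if (!all(dim(img) == size))
      stop_valid(sprintf("sample %d is %dx%d; expected %dx%d (resize first)",
                         idx[i], nrow(img), ncol(img), size, size))
    x[, , 1L, i] <- img
    y[, , 1L, i] <- sampleMask(s)
  }
  list(x = x, y = y)
}

.adam_state <- function(params) {
  e <- new.env(parent = emptyenv())
  e$t <- 0
  e$m <- lapply(params, function(p) array(0, dim(p$value) %||%
                                            length(p$value)))
  e$v <- lapply(params, function(p) array(0, dim(p$value) %||%
                                            length(p$value)))
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

.snapshot_model <- function(model) {
  list(weights = lapply(model@params, function(p) p$value),
       state = lapply(model@state, function(e) list(mean = e$mean,
                                                    var = e$var)))
}

.restore_model <- function(model, snap) {
  for (nm in names(snap$weights)) model@params[[nm]]$value <- snap$weights[[nm]]
  for (nm in names(snap$state)) {
    model@state[[nm]]$mean <- snap$state[[nm]]$mean
    model@state[[nm]]$var <- snap$state[[nm]]$var
  }
  invisible(model)
}

# Inference-mode probability maps for a stacked tensor, in chunks.
.predict_tensor <- function(model, x, chunk = 16L) {
  n <- dim(x)[4]
  out <- array(0, dim(x))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[, , , idx] <- .forward_net(
      model, ad_const(x[, , , idx, drop = FALSE]), mode = "eval")$value
  }
  out
}

#' Train the network
#'
#' Minimizes binary cross-entropy with Adam at the configured learning
#' rate, computing validation loss and the six ratio metrics (at threshold
#' 0.5, micro-aggregated) after every epoch. Training stops when the
#' validation loss has not improved for `patience` epochs, and the weights
#' and batch-norm statistics of the best epoch are restored, so the
#' returned model never carries weights from an epoch with a higher
#' validation loss. The model's parameter nodes are updated in place; the
#' trained model is also returned for convenience. A non-finite loss
#' aborts with a diagnostic.
#'
#' @param model a [ThrombusNet-class].
#' @param samples list of preprocessed [LabeledSample-class] objects whose
#'   images match the model's input size.
#' @param cfg a [TrainConfig-class].
#' @param splits optional index sets as returned by [splitDataset()];
#'   computed from `cfg` when missing.
#' @param verbose print a line per epoch.
#' @param .valLoss optional hook `function(epoch, model) -> numeric` that
#'   replaces the computed validation loss; used to exercise the
#'   early-stopping controller against a prescribed loss sequence.
#' @return list with elements `model` and `log` (a [TrainLog-class]).
#' @export
trainModel <- function(model, samples, cfg = trainConfig(), splits = NULL,
                       verbose = FALSE, .valLoss = NULL) {
  if (!is(model, "ThrombusNet")) stop_param("model must be a ThrombusNet")
  if (is.null(splits)) splits <- splitDataset(samples, cfg)
  size <- model@config@inputSize
  tr <- .stack_samples(samples, splits$train, size)
  va <- if (length(splits$val)) .stack_samples(samples, splits$val, size)
  st <- .adam_state(model@params)
  ntrain <- dim(tr$x)[4]
  hist_rows <- vector("list", cfg@epochs)
  best <- Inf
  best_epoch <- 0L
  best_snap <- NULL
  wait <- 0L
  stopped <- FALSE
  with_seed(cfg@seed, {
    for (epoch in seq_len(cfg@epochs)) {
      perm <- sample.int(ntrain)
      batch_losses <- numeric(0)
      for (start in seq(1L, ntrain, by = cfg@batchSize)) {
        idx <- perm[start:min(start + cfg@batchSize - 1L, ntrain)]
        xb <- ad_const(tr$x[, , , idx, drop = FALSE])
        yb <- tr$y[, , , idx, drop = FALSE]
        out <- .forward_net(model, xb, mode = "train")
        loss <- ad_bce(out, yb)
        if (!is.finite(loss$value))
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d", epoch))
        ad_backward(loss)
        .adam_step(model@params, st, cfg@learningRate)
        batch_losses <- c(batch_losses, loss$value)
      }
      .calibrateNorm(model, tr$x, cfg@batchSize)
      val_metrics <- rep(NA_real_, 6)
      if (!is.null(.valLoss)) {
        vl <- .valLoss(epoch, model)
      } else {
        if (is.null(va)) stop_valid("validation split is empty")
        pv <- .predict_tensor(model, va$x, chunk = cfg@batchSize)
        vl <- bceLoss(matrix(va$y, nrow = dim(va$y)[1]),
                      matrix(pv, nrow = dim(pv)[1]))
        pairs <- lapply(seq_len(dim(pv)[4]), function(i)
          list(truth = va$y[, , 1L, i],
               pred = thresholdProbabilities(pv[, , 1L, i], 0.5),
               prob = pv[, , 1L, i]))
        rep_ <- aggregateOverDataset(pairs, "micro")
        val_metrics <- c(rep_@accuracy, rep_@precision, rep_@sensitivity,
                         rep_@specificity, rep_@dice, rep_@iou)
      }
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch, trainLoss = mean(batch_losses), valLoss = vl,
        valAccuracy = val_metrics[1], valPrecision = val_metrics[2],
        valSensitivity = val_metrics[3], valSpecificity = val_metrics[4],
        valDice = val_metrics[5], valIoU = val_metrics[6])
      if (verbose)
        message(sprintf("epoch %d: train %.4f  val %.4f", epoch,
                        mean(batch_losses), vl))
      if (vl < best) {
        best <- vl
        best_epoch <- epoch
        best_snap <- .snapshot_model(model)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg@patience) {
          stopped <- TRUE
          break
        }
      }
    }
  })
  if (!is.null(best_snap)) .restore_model(model, best_snap)
  log <- new("TrainLog",
             history = do.call(rbind, hist_rows[!vapply(hist_rows, is.null,
                                                        logical(1))]),
             bestEpoch = best_epoch, stoppedEarly = stopped)
  list(model = model, log = log)
}

#' Evaluate a model on a sample split
#'
#' Inference-mode prediction over the split, thresholding, and
#' micro-aggregated metrics. Side-effect free: repeated calls agree
#' bit-wise.
#'
#' @param model a trained [ThrombusNet-class].
#' @param samples list of preprocessed [LabeledSample-class] objects (a
#'   split of the dataset).
#' @param threshold probability cutoff in (0, 1).
#' @return A [MetricReport-class].
#' @export
evaluateSplit <- function(model, samples,
                          threshold = model@config@threshold) {
  if (length(samples) == 0) stop_valid("cannot evaluate an empty split")
  size <- model@config@inputSize
  te <- .stack_samples(samples, seq_along(samples), size)
  pv <- .predict_tensor(model, te$x)
  pairs <- lapply(seq_len(dim(pv)[4]), function(i)
    list(truth = te$y[, , 1L, i],
         pred = thresholdProbabilities(pv[, , 1L, i], threshold),
         prob = pv[, , 1L, i]))
  aggregateOverDataset(pairs, "micro")
}

#' Write a training log to disk
#'
#' Writes the per-epoch history as a tab-separated table and a JSON
#' summary (best epoch, stopping flag, final metrics).
#'
#' @param log a [TrainLog-class].
#' @param path output path without extension.
#' @return invisibly, the written paths.
#' @export
writeTrainLog <- function(log, path) {
  tsv <- paste0(path, ".tsv")
  write.table(log@history, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  js <- paste0(path, ".json")
  jsonlite::write_json(
    list(bestEpoch = log@bestEpoch, stoppedEarly = log@stoppedEarly,
         epochs = nrow(log@history),
         bestValLoss = log@history$valLoss[log@bestEpoch]),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
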