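#' Pixel-wise confusion counts
#'
#' The four integers underlying every ratio metric: true positives,
#' true negatives, false positives and false negatives of a binary
#' prediction against a binary ground truth.
#'
#' @slot pCorrect true positives.
#' @slot nCorrect true negatives.
#' @slot pIncorrect false positives.
#' @slot nIncorrect false negatives.
#' @seealso [confusionCounts()], [computeMetrics()]
#' @export
setClass("ConfusionCounts", representation(
  pCorrect = "numeric", nCorrect = "numeric",
  pIncorrect = "numeric", nIncorrect = "numeric"
))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@pCorrect, object@nCorrect, object@pIncorrect,
         object@nIncorrect)
  if (any(v < 0) || any(v != round(v)))
    "counts must be non-negative integers"
  else TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d (total %d)\n",
              object@pCorrect, object@nCorrect, object@pIncorrect,
              object@nIncorrect, confusionTotal(object)))
})

#' @describeIn ConfusionCounts-class total compared pixels
#' @param x a `ConfusionCounts`
#' @export
confusionTotal <- function(x)
  x@pCorrect + x@nCorrect + x@pIncorrect + x@nIncorrect

#' @describeIn ConfusionCounts-class counts as a named vector (TP, TN, FP, FN)
#' @export
confusionVector <- function(x)
  c(TP = x@pCorrect, TN = x@nCorrect, FP = x@pIncorrect, FN = x@nIncorrect)

#' Segmentation metric report
#'
#' The six ratio metrics plus the binary cross-entropy loss. Ratios that
#' are undefined (0/0, e.g. precision with no predicted positives) are
#' reported as `NA` and named in `flags` rather than silently coerced to
#' 0 or 1.
#'
#' @slot accuracy,precision,sensitivity,specificity,dice,iou fractions in
#'   \[0, 1\], or `NA` when undefined.
#' @slot loss mean binary cross-entropy in nats (`NA` when no
#'   probabilities were supplied).
#' @slot flags names of the metrics that were undefined.
#' @export
setClass("MetricReport", representation(
  accuracy = "numeric", precision = "numeric", sensitivity = "numeric",
  specificity = "numeric", dice = "numeric", iou = "numeric",
  loss = "numeric", flags = "character"
))

setMethod("show", "MetricReport", function(object) {
  fmt <- function(v) ifelse(is.na(v), "undefined", sprintf("%.4f", v))
  cat("MetricReport\n")
  cat(sprintf("  accuracy    %s\n", fmt(object@accuracy)))
  cat(sprintf("  precision   %s\n", fmt(object@precision)))
  cat(sprintf("  sensitivity %s (recall)\n", fmt(object@sensitivity)))
  cat(sprintf("  specificity %s\n", fmt(object@specificity)))
  cat(sprintf("  dice        %s\n", fmt(object@dice)))
  cat(sprintf("  iou         %s\n", fmt(object@iou)))
  cat(sprintf("  loss        %s\n", fmt(object@loss)))
  if (length(object@flags))
    cat("  undefined:", paste(object@flags, collapse = ", "), "\n")
})

#' Metric report as a data frame
#'
#' @param report a [MetricReport-class].
#' @return one-row data frame with the seven metric columns.
#' @export
metricsAsDataFrame <- function(report) {
  data.frame(accuracy = report@accuracy, precision = report@precision,
             sensitivity = report@sensitivity,
             specificity = report@specificity, dice = report@dice,
             iou = report@iou, loss = report@loss)
}

.check_binary_mask <- function(m, what) {
  if (is.null(dim(m)) || !is.numeric(m))
    stop_valid(sprintf("%s must be a numeric matrix", what))
  if (!all(m %in% c(0, 1)))
    stop_valid(sprintf("%s must be binary (values in {0, 1})", what))
  invisible(m)
}

#' Count pixel-wise agreement between two binary masks
#'
#' @param truth binary ground-truth matrix.
#' @param pred binary prediction matrix of the same shape.
#' @return A [ConfusionCounts-class] with integer-exact counts.
#' @examples
#' f <- generateConfusionFixture(10, 80, 5, 5)
#' confusionCounts(f$truth, f$pred)
#' @export
confusionCounts <- function(truth, pred) {
  .check_binary_mask(truth, "truth")
  .check_binary_mask(pred, "pred")
  if (!identical(dim(truth), dim(pred)))
    stop_valid("truth and pred must have identical shapes")
  t1 <- truth == 1
  p1 <- pred == 1
  new("ConfusionCounts",
      pCorrect = sum(t1 & p1), nCorrect = sum(!t1 & !p1),
      pIncorrect = sum(!t1 & p1), nIncorrect = sum(t1 & !p1))
}

#' Compute the six ratio metrics from confusion counts
#'
#' accuracy = (TP+TN)/total, precision = TP/(TP+FP),
#' sensitivity (= recall) = TP/(TP+FN), specificity = TN/(TN+FP),
#' Dice = 2TP/(2TP+FP+FN), IoU = TP/(TP+FP+FN). Any 0/0 ratio is reported
#' as `NA` and listed in the report's `flags`. Dice and IoU computed from
#' the same counts satisfy Dice = 2 IoU / (1 + IoU).
#'
#' @param counts a [ConfusionCounts-class].
#' @param loss optional binary cross-entropy to carry in the report.
#' @return A [MetricReport-class].
#' @export
computeMetrics <- function(counts, loss = NA_real_) {
  if (!is(counts, "ConfusionCounts"))
    stop_valid("counts must be a ConfusionCounts object")
  tp <- counts@pCorrect; tn <- counts@nCorrect
  fp <- counts@pIncorrect; fn <- counts@nIncorrect
  total <- tp + tn + fp + fn
  if (total <= 0) stop_valid("total pixel count must be > 0")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- ratio(tp + tn, total)
  prec <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  dice <- ratio(2 * tp, 2 * tp + fp + fn)
  iou <- ratio(tp, tp + fp + fn)
  vals <- c(accuracy = acc, precision = prec, sensitivity = sens,
            specificity = spec, dice = dice, iou = iou)
  new("MetricReport", accuracy = acc, precision = prec, sensitivity = sens,
      specificity = spec, dice = dice, iou = iou, loss = loss,
      flags = names(vals)[is.na(vals)])
}

#' Binary cross-entropy between a mask and a probability map
#'
#' Mean negative Bernoulli log-likelihood in nats over all pixels:
#' \deqn{-\frac{1}{N}\sum_i [y_i \log \hat y_i + (1-y_i)\log(1-\hat y_i)]}
#' with probabilities clipped to \[eps, 1-eps\] before the logarithms.
#'
#' @param truth binary matrix of actual labels.
#' @param prob matrix of predicted probabilities in \[0, 1\], same shape.
#' @param eps clipping floor (default 1e-7).
#' @return non-negative scalar.
#' @export
bceLoss <- function(truth, prob, eps = 1e-7) {
  .check_binary_mask(truth, "truth")
  if (!identical(dim(truth), dim(prob)))
    stop_valid("truth and prob must have identical shapes")
  if (any(prob < 0 | prob > 1))
    stop_valid("probabilities must lie in [0, 1]")
  pc <- pmin(pmax(prob, eps), 1 - eps)
  -mean(truth * log(pc) + (1 - truth) * log(1 - pc))
}

#' Aggregate metrics over a dataset
#'
#' Micro aggregation (the default) pools the confusion counts of all pairs
#' and applies the formulas once, and averages the loss over all pixels of
#' all pairs; this matches how accuracy and loss are conventionally logged
#' during training. Macro aggregation (`mode = "macro"`) instead averages
#' per-image metrics, dropping undefined values.
#'
#' @param pairs non-empty list; each element a list with binary `truth` and
#'   `pred` matrices and optionally a `prob` matrix for the loss.
#' @param mode "micro" or "macro".
#' @return A [MetricReport-class].
#' @export
aggregateOverDataset <- function(pairs, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  if (!is.list(pairs) || length(pairs) == 0)
    stop_valid("pairs must be a non-empty list")
  counts <- lapply(pairs, function(p) confusionCounts(p$truth, p$pred))
  has_prob <- vapply(pairs, function(p) !is.null(p$prob), logical(1))
  if (mode == "micro") {
    tot <- new("ConfusionCounts",
      pCorrect = sum(vapply(counts, slot, 0, "pCorrect")),
      nCorrect = sum(vapply(counts, slot, 0, "nCorrect")),
      pIncorrect = sum(vapply(counts, slot, 0, "pIncorrect")),
      nIncorrect = sum(vapply(counts, slot, 0, "nIncorrect")))
    loss <- NA_real_
    if (all(has_prob)) {
      npix <- vapply(pairs, function(p) length(p$truth), 0)
      li <- vapply(pairs, function(p) bceLoss(p$truth, p$prob), 0)
      loss <- sum(li * npix) / sum(npix)
    }
    computeMetrics(tot, loss = loss)
  } else {
    reps <- lapply(counts, computeMetrics)
    avg <- function(f) {
      v <- vapply(reps, slot, 0, f)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    loss <- if (all(has_prob))
      mean(vapply(pairs, function(p) bceLoss(p$truth, p$prob), 0))
    else NA_real_
    vals <- c(accuracy = avg("accuracy"), precision = avg("precision"),
              sensitivity = avg("sensitivity"),
              specificity = avg("specificity"),
              dice = avg("dice"), iou = avg("iou"))
    new("MetricReport", accuracy = vals[["accuracy"]],
        precision = vals[["precision"]],
        sensitivity = vals[["sensitivity"]],
        specificity = vals[["specificity"]], dice = vals[["dice"]],
        iou = vals[["iou"]], loss = loss,
        flags = names(vals)[is.na(vals)])
  }
}

#' Write a metric report to disk
#'
#' Writes the report as a tab-separated table (metric, value) and/or JSON.
#'
#' @param report a [MetricReport-class].
#' @param path output path without extension; `.tsv` / `.json` are added.
#' @param formats subset of c("tsv", "json").
#' @return invisibly, the written paths.
#' @export
writeMetricReport <- function(report, path, formats = c("tsv", "json")) {
  df <- metricsAsDataFrame(report)
  out <- character(0)
  if ("tsv" %in% formats) {
    p <- paste0(path, ".tsv")
    long <- data.frame(metric = names(df), value = as.numeric(df[1, ]))
    write.table(long, p, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, p)
  }
  if ("json" %in% formats) {
    p <- paste0(path, ".json")
    jsonlite::write_json(as.list(df), p, auto_unbox = TRUE, digits = NA,
                         na = "null")
    out <- c(out, p)
  }
  invisible(out)
}
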