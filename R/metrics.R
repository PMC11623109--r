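#' Binary cross-entropy loss
#'
#' Mean pixelwise binary cross-entropy
#' `L = -(1/N) * sum(y*log(p) + (1-y)*log(1-p))`. Probabilities are clamped
#' to `[1e-7, 1 - 1e-7]` before the logs so perfectly confident predictions
#' cannot produce infinities.
#'
#' @param truth binary vector/matrix of ground-truth labels.
#' @param probs predicted probabilities with the same shape.
#' @return non-negative scalar loss.
#' @examples
#' bceLoss(c(1, 0, 1), c(0.9, 0.2, 0.8))  # 0.18388...
#' @export
bceLoss <- function(truth, probs) {
  if (length(truth) == 0) stop("empty input")
  if (!identical(dim(truth), dim(probs)) || length(truth) != length(probs))
    stop("truth and probs dims do not match")
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Pixelwise confusion counts
#'
#' @param pred,truth binary masks of identical dims.
#' @return a [ConfusionCounts-class] whose counts sum to the pixel count.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth dims do not match")
  p <- as.vector(pred); t <- as.vector(truth)
  new("ConfusionCounts",
      tp = sum(p == 1 & t == 1), tn = sum(p == 0 & t == 0),
      fp = sum(p == 1 & t == 0), fn = sum(p == 0 & t == 1))
}

#' Confusion-matrix metrics
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(FP+TN)`, precision `TP/(FP+TP)` and F1 `2TP/(2TP+FP+FN)`.
#' Degenerate denominators are handled as: no positives in truth gives
#' sensitivity 1; no negatives gives specificity 1; no positive predictions
#' gives precision 1 when nothing was missed (FN = 0), else 0; F1 of two
#' empty masks is 1.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named numeric vector `acc`, `sen`, `spe`, `pre`, `f1`.
#' @export
basicMetrics <- function(counts) {
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty confusion counts")
  sen <- if (tp + fn == 0) 1 else tp / (tp + fn)
  spe <- if (fp + tn == 0) 1 else tn / (fp + tn)
  pre <- if (tp + fp == 0) { if (fn == 0) 1 else 0 } else tp / (tp + fp)
  f1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  c(acc = (tp + tn) / n, sen = sen, spe = spe, pre = pre, f1 = f1)
}

#' Dice coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks score 1. On binary masks this
#' is algebraically identical to the F1 score computed from the confusion
#' counts of the same pair.
#'
#' @param pred,truth binary masks of identical dims.
#' @return scalar in `[0,1]`.
#' @export
dice <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth dims do not match")
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred * truth) / denom
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve by the pairwise-ranking (Mann-Whitney)
#' definition: the probability that a randomly chosen foreground pixel is
#' scored above a randomly chosen background pixel, with ties counting 1/2.
#' Exact for finite samples and invariant under strictly monotone transforms
#' of the scores.
#'
#' @param probs predicted scores/probabilities.
#' @param truth binary labels of the same length/dims.
#' @return scalar AUC in `[0,1]`.
#' @export
rocAuc <- function(probs, truth) {
  p <- as.vector(probs); t <- as.vector(truth)
  if (length(p) != length(t)) stop("probs and truth lengths differ")
  npos <- sum(t == 1); nneg <- sum(t == 0)
  if (npos == 0 || nneg == 0)
    stop("truth must contain both classes for an ROC AUC")
  r <- rank(p, ties.method = "average")
  (sum(r[t == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Build a single-fold metric report
#'
#' @param metrics named numeric vector containing `acc`, `sen`, `spe`,
#'   `pre`, `f1`, `dice`, `auc` (missing entries become NA).
#' @param fold fold id.
#' @return a [MetricReport-class] with one fold.
#' @export
metricReport <- function(metrics, fold = 1L) {
  v <- setNames(rep(NA_real_, length(metricNames())), metricNames())
  v[intersect(names(metrics), names(v))] <-
    metrics[intersect(names(metrics), names(v))]
  pf <- cbind(data.frame(fold = as.integer(fold)), as.data.frame(as.list(v)))
  new("MetricReport", perFold = pf, mean = v,
      sd = setNames(rep(NA_real_, length(v)), names(v)), nFolds = 1L)
}

#' Aggregate per-fold metric reports
#'
#' Unweighted mean and sample standard deviation per metric across folds.
#'
#' @param reports list of single-fold [MetricReport-class] objects.
#' @return an aggregated [MetricReport-class].
#' @export
aggregateFolds <- function(reports) {
  if (length(reports) == 0) stop("no reports to aggregate")
  pf <- do.call(rbind, lapply(seq_along(reports), function(i) {
    x <- reports[[i]]@perFold
    x$fold <- i
    x
  }))
  m <- vapply(metricNames(), function(nm) mean(pf[[nm]]), numeric(1))
  s <- vapply(metricNames(), function(nm)
    if (nrow(pf) > 1) sd(pf[[nm]]) else NA_real_, numeric(1))
  new("MetricReport", perFold = pf, mean = m, sd = s,
      nFolds = length(reports))
}

#' Write a metric report as CSV or JSON
#'
#' One row per fold plus a `mean` and an `sd` row.
#'
#' @param report a [MetricReport-class].
#' @param path destination; `.json` selects JSON, anything else CSV.
#' @return the written data.frame, invisibly.
#' @export
writeMetricReport <- function(report, path) {
  pf <- report@perFold
  pf$fold <- as.character(pf$fold)
  summ <- data.frame(fold = c("mean", "sd"),
                     rbind(as.data.frame(as.list(report@mean)),
                           as.data.frame(as.list(report@sd))))
  tab <- rbind(pf, summ)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, dataframe = "rows", pretty = TRUE,
                         na = "null", digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(tab)
}

#' @describeIn metricReport-accessors fold-mean metric vector.
#' @export
setMethod("meanMetrics", "MetricReport", function(object) object@mean)

#' @describeIn metricReport-accessors fold standard deviations.
#' @export
setMethod("sdMetrics", "MetricReport", function(object) object@sd)

#' @describeIn metricReport-accessors per-fold data.frame.
#' @export
setMethod("perFoldMetrics", "MetricReport", function(object) object@perFold)

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport over %d fold(s)\n", object@nFolds))
  for (nm in metricNames()) {
    if (is.na(object@mean[nm])) next
    if (object@nFolds > 1 && !is.na(object@sd[nm]))
      cat(sprintf("  %-4s %.4f +/- %.4f\n", nm, object@mean[nm], object@sd[nm]))
    else
      cat(sprintf("  %-4s %.4f\n", nm, object@mean[nm]))
  }
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%g TN=%g FP=%g FN=%g (N=%g)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})
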