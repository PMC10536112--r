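# Pixelwise agreement between predicted and ground-truth capillary masks.

#' Pixelwise confusion counts between two binary masks
#'
#' White (1) is the positive, capillary class.
#'
#' @param pred,truth 0/1 matrices with identical dimensions.
#' @return list of class `confusion_counts` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("mask dimensions differ")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("mask values must be strictly {0, 1}")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Jaccard index (intersection over union of the foregrounds), sensitivity,
#' specificity and accuracy. When both masks are empty the Jaccard index is
#' defined as 1 (perfect agreement); when exactly one is empty it is 0.
#' Sensitivity (specificity) is reported as `NA` when the mask pair contains
#' no positive (negative) pixels.
#'
#' @param counts `confusion_counts`.
#' @return list of class `metrics_report` with fields `jaccard`,
#'   `sensitivity`, `specificity`, `accuracy`, `counts`.
#' @export
report <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty masks")
  jac <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1.0
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total
  structure(list(jaccard = jac, sensitivity = sens, specificity = spec,
                 accuracy = acc, counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics: Jaccard %.4f | sensitivity %.4f | specificity %.4f | accuracy %.4f\n",
    x$jaccard, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Evaluate a predicted mask against ground truth
#'
#' Convenience wrapper: [confusion()] then [report()].
#'
#' @inheritParams confusion
#' @return `metrics_report`.
#' @export
evaluate_masks <- function(pred, truth) report(confusion(pred, truth))

#' Aggregate per-fold metrics across a cross-validation
#'
#' Two summaries are produced: the unweighted mean of the per-fold metric
#' values (`mean`, the headline figure) and metrics recomputed from the
#' pooled pixel counts of all folds (`pooled`). They coincide only when
#' folds have equal size and composition, so both are reported.
#'
#' @param folds list of fold results, each carrying a `metrics` field
#'   (`metrics_report`), e.g. from [train_loocv()].
#' @return list with `mean` (named numeric vector) and `pooled`
#'   (`metrics_report`).
#' @export
aggregate_folds <- function(folds) {
  if (length(folds) == 0) stop("no folds to aggregate")
  ms <- lapply(folds, function(f) f$metrics)
  take <- function(field) vapply(ms, function(m) m[[field]], 0)
  mean_metrics <- c(jaccard = mean(take("jaccard")),
                    sensitivity = mean(take("sensitivity")),
                    specificity = mean(take("specificity")),
                    accuracy = mean(take("accuracy")))
  pooled <- structure(list(
    tp = sum(take_count(ms, "tp")), fp = sum(take_count(ms, "fp")),
    fn = sum(take_count(ms, "fn")), tn = sum(take_count(ms, "tn"))),
    class = "confusion_counts")
  list(mean = mean_metrics, pooled = report(pooled))
}

take_count <- function(ms, field)
  vapply(ms, function(m) m$counts[[field]], 0)
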