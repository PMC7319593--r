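# Classification metrics.
#
# SN = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/total,
# F-value = 2*TP/(2*TP+FP+FN),
# MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)).
# Zero-denominator conventions (kept bounded so repeat-averaging stays
# well-defined): SN, SP -> 0 when their denominator is 0; F -> 0 when
# 2TP+FP+FN = 0; MCC -> 0 when any marginal is 0.

#' Confusion counts for binary predictions
#'
#' @param truth,estimate Equal-length 0/1 vectors (1 = positive class).
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length", class = "acr_input_error")
  }
  if (length(truth) == 0L) {
    abort("empty label vectors", class = "acr_input_error")
  }
  if (!all(truth %in% c(0, 1)) || !all(estimate %in% c(0, 1))) {
    abort("labels must be 0/1", class = "acr_input_error")
  }
  tibble(
    tp = sum(truth == 1 & estimate == 1),
    tn = sum(truth == 0 & estimate == 0),
    fp = sum(truth == 0 & estimate == 1),
    fn = sum(truth == 1 & estimate == 0)
  )
}

#' Confusion-derived performance metrics
#'
#' Computes sensitivity, specificity, accuracy, F-value and the Matthews
#' correlation coefficient from a confusion table.
#'
#' @param counts A one-row data frame (or list) with `tp`, `tn`, `fp`, `fn`.
#' @return A one-row tibble: `sn`, `sp`, `acc`, `f_value`, `mcc`, plus the
#'   four counts.
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  if (any(c(tp, tn, fp, fn) < 0) || tp + tn + fp + fn < 1) {
    abort("confusion counts must be non-negative and sum to >= 1",
          class = "acr_input_error")
  }
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  f_value <- safe_div(2 * tp, 2 * tp + fp + fn)
  denom <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else ((tp * tn) - (fn * fp)) / sqrt(denom)
  tibble(sn = sn, sp = sp, acc = acc, f_value = f_value, mcc = mcc,
         tp = tp, tn = tn, fp = fp, fn = fn)
}

#' ROC curve and AUC
#'
#' `roc_curve()` sweeps every distinct score as a threshold (prediction
#' positive when score >= threshold) and returns the (FPR, TPR) points;
#' `roc_auc()` integrates the curve by the trapezoidal rule, which equals the
#' probability that a random positive outscores a random negative, counting
#' ties as 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 truth labels; both classes must be present.
#' @return `roc_curve()`: a tibble of class `acr_roc` with columns
#'   `threshold`, `fpr`, `tpr`; `roc_auc()`: a single number in `[0, 1]`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length", class = "acr_input_error")
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2L) {
    abort("labels must be 0/1 with both classes present", class = "acr_input_error")
  }
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # cumulative counts at each distinct threshold (last index of each tie run)
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l == 1)[last]
  fp <- cumsum(l == 0)[last]
  out <- tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp / nn),
    tpr = c(0, tp / np)
  )
  class(out) <- c("acr_roc", class(out))
  out
}

#' @rdname roc_curve
#' @export
roc_auc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + rc$tpr[-1]) / 2)
}

#' Plot a ROC curve
#'
#' @param object An `acr_roc` tibble from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot acr_roc
#' @export
autoplot.acr_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}
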