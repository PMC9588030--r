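#' Confusion-matrix metrics with Wilson confidence interval
#'
#' For binary labels (positive class `1`): accuracy with its Wilson 95%
#' interval, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and
#' Cohen's kappa `(po - pe)/(1 - pe)` with the chance agreement `pe`
#' computed from the marginals.
#'
#' @param y_true,y_pred Equal-length binary vectors in `{0, 1}`.
#' @param conf_level Confidence level for the accuracy interval.
#' @return A list with `accuracy`, `ci_lower`, `ci_upper`, `sensitivity`,
#'   `specificity`, `kappa`, and the counts `tp`, `fn`, `fp`, `tn`.
#'   Sensitivity (specificity) is `NA` when no positives (negatives) exist.
#' @export
confusion_metrics <- function(y_true, y_pred, conf_level = 0.95) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  n <- tp + fn + fp + tn
  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  po <- acc
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  kappa <- if (pe >= 1) 0 else (po - pe) / (1 - pe)
  ci <- wilson_interval(tp + tn, n, conf_level)
  list(accuracy = acc, ci_lower = ci[1], ci_upper = ci[2],
       sensitivity = sens, specificity = spec, kappa = kappa,
       tp = tp, fn = fn, fp = fp, tn = tn)
}

wilson_interval <- function(k, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Area under the ROC curve
#'
#' Computed through the rank (Mann-Whitney) formulation with midranks for
#' ties, equivalent to the trapezoidal area under the ROC curve of the
#' decision values.
#'
#' @param y_true Binary labels in `{0, 1}`; both classes must be present.
#' @param decision_values Numeric scores; larger means more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, decision_values) {
  stopifnot(length(y_true) == length(decision_values))
  y_true <- as.integer(y_true)
  ok <- !is.na(decision_values) & !is.na(y_true)
  y_true <- y_true[ok]; decision_values <- decision_values[ok]
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(decision_values, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Class imbalance ratio
#'
#' The majority-class count divided by the total count, so a balanced
#' dataset has ratio 0.5 and the ratio lies in \[0.5, 1\].
#'
#' @param class_counts Two non-negative counts (any order), sum > 0.
#' @return The imbalance ratio.
#' @export
imbalance_ratio <- function(class_counts) {
  stopifnot(length(class_counts) == 2, all(class_counts >= 0))
  total <- sum(class_counts)
  if (total == 0) stop("total class count is zero")
  max(class_counts) / total
}

#' Full classifier evaluation
#'
#' Bundles [confusion_metrics()], [roc_auc()] and [imbalance_ratio()] into
#' one record per evaluated model.
#'
#' @inheritParams confusion_metrics
#' @param decision_values Scores for the ROC; if `NULL`, AUC is `NA`.
#' @return A list of class `classifier_evaluation`.
#' @export
classifier_evaluation <- function(y_true, y_pred, decision_values = NULL) {
  cm <- confusion_metrics(y_true, y_pred)
  auc <- if (is.null(decision_values)) NA_real_ else roc_auc(y_true, decision_values)
  structure(c(cm, list(
    auc = auc,
    imbalance_ratio = imbalance_ratio(c(sum(y_true == 1), sum(y_true == 0))))),
    class = "classifier_evaluation")
}
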