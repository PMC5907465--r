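#' One-vs-rest confusion counts and misclassification matrix
#'
#' For each cause j computes TP (true cause j, predicted j), FN (true j,
#' predicted other), FP (true other, predicted j) and TN, plus the full
#' N x N misclassification matrix with true causes in rows and predicted
#' causes in columns.
#'
#' @param true_causes character vector of gold-standard causes.
#' @param predicted_causes character vector of predicted causes, same length.
#' @param cause_list a [cause_list()]; all labels must belong to it.
#' @return A `confusion_summary`: list with vectors `tp`, `fn`, `fp`, `tn`
#'   (named by cause), matrix `misclass`, and `n_records`.
#' @examples
#' cl <- cause_list(c("A", "B", "C"), "adult")
#' confusion_counts(c("A", "A", "B", "C"), c("A", "B", "B", "B"), cl)
#' @export
confusion_counts <- function(true_causes, predicted_causes, cause_list) {
  stopifnot(inherits(cause_list, "cause_list"))
  true_causes <- as.character(true_causes)
  predicted_causes <- as.character(predicted_causes)
  if (length(true_causes) == 0L) {
    stop("label sequences must be non-empty", call. = FALSE)
  }
  if (length(true_causes) != length(predicted_causes)) {
    stop("true and predicted label sequences must have equal length",
         call. = FALSE)
  }
  causes <- as.character(cause_list)
  if (any(!(true_causes %in% causes)) || any(!(predicted_causes %in% causes))) {
    stop("labels must belong to the cause list", call. = FALSE)
  }
  tf <- factor(true_causes, levels = causes)
  pf <- factor(predicted_causes, levels = causes)
  M <- table(true = tf, predicted = pf)
  M <- matrix(as.integer(M), nrow = length(causes),
              dimnames = list(true = causes, predicted = causes))
  n <- length(true_causes)
  tp <- diag(M)
  fn <- rowSums(M) - tp
  fp <- colSums(M) - tp
  tn <- n - tp - fn - fp
  structure(
    list(tp = tp, fn = fn, fp = fp, tn = tn, misclass = M, n_records = n),
    class = "confusion_summary"
  )
}

#' Chance-corrected concordance per cause
#'
#' CCC_j = (TP_j / (TP_j + FN_j) - 1/N) / (1 - 1/N): per-cause sensitivity
#' rescaled so 0 equals random guessing among N causes and 1 equals perfect
#' detection. The minimum attainable value is -1/(N-1) (sensitivity 0).
#' Causes with no true cases (TP + FN = 0) are undefined and returned as
#' `NA`; they are excluded from any overall aggregation.
#'
#' @param confusion a `confusion_summary` from [confusion_counts()], or any
#'   list with `tp` and `fn` vectors.
#' @param n_causes number of causes N (>= 2); defaults to the length of
#'   `confusion$tp`.
#' @return Named numeric vector of CCC values in \[-1/(N-1), 1\], `NA` where
#'   undefined.
#' @export
ccc_per_cause <- function(confusion, n_causes = length(confusion$tp)) {
  if (n_causes < 2L) stop("CCC requires N >= 2 causes", call. = FALSE)
  tp <- confusion$tp
  fn <- confusion$fn
  denom <- tp + fn
  sens <- ifelse(denom > 0, tp / denom, NA_real_)
  ccc <- (sens - 1 / n_causes) / (1 - 1 / n_causes)
  stopifnot(all(is.na(ccc) | (ccc >= -1 / (n_causes - 1) - 1e-12 & ccc <= 1 + 1e-12)))
  ccc
}

#' Overall chance-corrected concordance
#'
#' Aggregates per-cause CCC over the causes for which it is defined, by mean
#' (default) or median.
#'
#' @param ccc_by_cause numeric vector from [ccc_per_cause()]; `NA` entries
#'   (undefined causes) are dropped.
#' @param method `"mean"` or `"median"`.
#' @return Scalar overall CCC.
#' @export
overall_ccc <- function(ccc_by_cause, method = c("mean", "median")) {
  method <- match.arg(method)
  x <- ccc_by_cause[!is.na(ccc_by_cause)]
  if (length(x) == 0L) {
    stop("CCC is undefined for every cause", call. = FALSE)
  }
  if (method == "mean") mean(x) else stats::median(x)
}

#' Cause-specific mortality fractions from labels
#'
#' @param labels character vector of cause labels.
#' @param cause_list a [cause_list()].
#' @return Named probability vector over the cause list (sums to 1).
#' @export
csmf_from_labels <- function(labels, cause_list) {
  stopifnot(inherits(cause_list, "cause_list"))
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("labels must be non-empty", call. = FALSE)
  causes <- as.character(cause_list)
  if (any(!(labels %in% causes))) {
    stop("labels must belong to the cause list", call. = FALSE)
  }
  counts <- table(factor(labels, levels = causes))
  out <- as.numeric(counts) / length(labels)
  names(out) <- causes
  out
}

#' CSMF accuracy
#'
#' 1 - sum_j |CSMF_true_j - CSMF_pred_j| / (2 (1 - min_j CSMF_true_j)):
#' one minus the L1 distance between true and predicted cause fractions,
#' normalised by its maximum attainable value for the given true fractions,
#' so the result lies in \[0, 1\] with 1 for a perfect match.
#'
#' @param csmf_true true cause fraction vector (sums to 1).
#' @param csmf_pred predicted cause fraction vector (same length, sums to 1).
#' @return Scalar in \[0, 1\].
#' @examples
#' csmf_accuracy(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5))  # 0.625
#' @export
csmf_accuracy <- function(csmf_true, csmf_pred) {
  if (length(csmf_true) != length(csmf_pred)) {
    stop("CSMF vectors must have equal length", call. = FALSE)
  }
  if (abs(sum(csmf_true) - 1) > 1e-9 || abs(sum(csmf_pred) - 1) > 1e-9) {
    stop("CSMF vectors must sum to 1", call. = FALSE)
  }
  denom <- 2 * (1 - min(csmf_true))
  if (denom == 0) {
    stop("CSMF accuracy undefined: all mass on a single cause", call. = FALSE)
  }
  1 - sum(abs(csmf_true - csmf_pred)) / denom
}

#' Chance-corrected CSMF accuracy
#'
#' Rescales CSMF accuracy so that 0 corresponds to the chance level
#' 1 - exp(-1) ~ 0.632 attained by random cause allocation under
#' Dirichlet-distributed true fractions, and 1 remains perfect. Values below
#' 0 mean worse than chance.
#'
#' @param csmf_acc CSMF accuracy in \[0, 1\].
#' @return Scalar <= 1.
#' @export
cccsmf_accuracy <- function(csmf_acc) {
  stopifnot(csmf_acc >= 0, csmf_acc <= 1)
  chance <- 1 - exp(-1)
  (csmf_acc - chance) / (1 - chance)
}

#' Per-cause sensitivity and specificity
#'
#' sens_j = TP_j / (TP_j + FN_j); spec_j = TN_j / (TN_j + FP_j). Causes with
#' no true cases have undefined sensitivity (`NA`, excluded from the
#' median).
#'
#' @param confusion a `confusion_summary` from [confusion_counts()].
#' @return List with `sensitivity`, `specificity` (named vectors) and
#'   `sensitivity_median`, `specificity_median`.
#' @export
sensitivity_specificity <- function(confusion) {
  tp <- confusion$tp; fn <- confusion$fn
  fp <- confusion$fp; tn <- confusion$tn
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  list(sensitivity = sens, specificity = spec,
       sensitivity_median = stats::median(sens, na.rm = TRUE),
       specificity_median = stats::median(spec, na.rm = TRUE))
}

#' Full metric report for one evaluation
#'
#' Computes every individual- and population-level statistic for one set of
#' predictions: per-cause and overall CCC (mean and median), CSMF accuracy,
#' CCCSMF accuracy, per-cause and median sensitivity/specificity, and the
#' misclassification matrix.
#'
#' @param true_causes gold-standard cause labels.
#' @param predicted_causes predicted cause labels, same length.
#' @param cause_list a [cause_list()].
#' @return A `metric_report` list.
#' @export
metric_report <- function(true_causes, predicted_causes, cause_list) {
  conf <- confusion_counts(true_causes, predicted_causes, cause_list)
  n_causes <- length(cause_list)
  ccc <- ccc_per_cause(conf, n_causes)
  ss <- sensitivity_specificity(conf)
  csmf_true <- csmf_from_labels(true_causes, cause_list)
  csmf_pred <- csmf_from_labels(predicted_causes, cause_list)
  acc <- csmf_accuracy(csmf_true, csmf_pred)
  structure(
    list(
      confusion = conf,
      ccc_by_cause = ccc,
      ccc_overall_mean = overall_ccc(ccc, "mean"),
      ccc_overall_median = overall_ccc(ccc, "median"),
      csmf_true = csmf_true,
      csmf_pred = csmf_pred,
      csmf_accuracy = acc,
      cccsmf_accuracy = cccsmf_accuracy(acc),
      sensitivity_by_cause = ss$sensitivity,
      specificity_by_cause = ss$specificity,
      sensitivity_median = ss$sensitivity_median,
      specificity_median = ss$specificity_median
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  cat(sprintf("  overall CCC (mean):   %6.1f%%\n", 100 * x$ccc_overall_mean))
  cat(sprintf("  overall CCC (median): %6.1f%%\n", 100 * x$ccc_overall_median))
  cat(sprintf("  CSMF accuracy:        %6.1f%%\n", 100 * x$csmf_accuracy))
  cat(sprintf("  CCCSMF accuracy:      %6.1f%%\n", 100 * x$cccsmf_accuracy))
  cat(sprintf("  median sens / spec:   %.3f / %.3f\n",
              x$sensitivity_median, x$specificity_median))
  invisible(x)
}
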