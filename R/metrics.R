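# Binary classification metrics used throughout: specificity,
# sensitivity, accuracy, F1, Matthews correlation, balanced accuracy
# (the model-selection criterion) and rank-based ROC AUC.

#' Confusion counts from predicted probabilities
#'
#' Predictions at or above `threshold` count as positive (the tie at the
#' threshold is inclusive, so a probability of exactly 0.5 is a predicted
#' positive under the default).
#'
#' @param probs Numeric vector of predicted probabilities.
#' @param labels Integer/numeric vector of observed labels in `{0, 1}`.
#' @param threshold Decision threshold, default 0.5.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
#' @examples
#' confusion_from_predictions(c(0.9, 0.1), c(1, 0))
confusion_from_predictions <- function(probs, labels, threshold = 0.5) {
  stopifnot(length(probs) == length(labels), length(probs) > 0,
            all(labels %in% c(0, 1)))
  pred <- as.integer(probs >= threshold)
  tibble::tibble(
    tp = sum(pred == 1L & labels == 1),
    tn = sum(pred == 0L & labels == 0),
    fp = sum(pred == 1L & labels == 0),
    fn = sum(pred == 0L & labels == 1)
  )
}

safe_ratio <- function(num, den) if (den > 0) num / den else 0

#' Threshold metrics from confusion counts
#'
#' Computes SP = TN/(TN+FP), SE = TP/(TP+FN), ACC, F1 = 2TP/(2TP+FN+FP),
#' MCC, and BA = (SE+SP)/2. Ratios with an empty denominator are reported
#' as 0 and flagged via the `degenerate` column so batch aggregation never
#' fails while the condition stays auditable.
#'
#' @param counts A one-row data frame with `tp`, `tn`, `fp`, `fn` (as
#'   produced by [confusion_from_predictions()]).
#' @return A one-row tibble with `acc`, `f1`, `ba`, `se`, `sp`, `mcc`,
#'   `degenerate`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp[[1]]; tn <- counts$tn[[1]]
  fp <- counts$fp[[1]]; fn <- counts$fn[[1]]
  total <- tp + tn + fp + fn
  stopifnot(total >= 1)
  degenerate <- (tn + fp) == 0 || (tp + fn) == 0 ||
    (tp + fp) == 0 || (tn + fn) == 0
  sp <- safe_ratio(tn, tn + fp)
  se <- safe_ratio(tp, tp + fn)
  mcc_den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tn + fp)
  mcc <- if (mcc_den > 0) (tp * tn - fn * fp) / mcc_den else 0
  tibble::tibble(
    acc = (tp + tn) / total,
    f1 = safe_ratio(2 * tp, 2 * tp + fn + fp),
    ba = (se + sp) / 2,
    se = se,
    sp = sp,
    mcc = mcc,
    degenerate = degenerate
  )
}

#' Rank-based ROC AUC
#'
#' The area under the ROC curve computed as the Mann-Whitney U statistic
#' divided by `n1 * n0`, with mid-ranks for tied scores.
#'
#' @inheritParams confusion_from_predictions
#' @return A single numeric value in `[0, 1]`.
#' @export
compute_auc <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC is undefined when only one class is present", call. = FALSE)
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full per-task metrics report
#'
#' Combines the threshold metrics with AUC. AUC is `NA` (and flagged
#' degenerate) when only one class is present.
#'
#' @inheritParams confusion_from_predictions
#' @return A one-row tibble with `acc`, `f1`, `ba`, `se`, `sp`, `mcc`,
#'   `auc`, `n`, `degenerate`.
#' @export
metrics_report <- function(probs, labels, threshold = 0.5) {
  rep <- compute_metrics(confusion_from_predictions(probs, labels, threshold))
  auc <- if (sum(labels == 1) > 0 && sum(labels == 0) > 0) {
    compute_auc(probs, labels)
  } else {
    NA_real_
  }
  dplyr::mutate(rep, auc = auc, n = length(probs),
                degenerate = .data$degenerate | is.na(auc))
}
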