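#' Causal-validity metrics
#'
#' PEHE (root mean squared error of individual effects), ATE bias and error,
#' ITE R-squared, ITE MAE, standard deviation of the estimated effects, and
#' the estimated ATE (mean of the predicted effects).
#'
#' @param tau_hat predicted individual effects.
#' @param tau_true ground-truth individual effects, same length (`n >= 2`).
#' @return a one-row tibble with columns `pehe`, `ate_error`, `ate_bias`,
#'   `estimated_ate`, `ite_r2` (NA when the truth is constant), `ite_mae`,
#'   `ite_std`.
#' @export
causal_metrics <- function(tau_hat, tau_true) {
  assert_that(length(tau_hat) == length(tau_true) && length(tau_hat) >= 2,
              "need equal-length vectors with n >= 2")
  err <- tau_hat - tau_true
  sst <- sum((tau_true - mean(tau_true))^2)
  tibble::tibble(
    pehe = sqrt(mean(err^2)),
    ate_bias = mean(tau_hat) - mean(tau_true),
    ate_error = abs(mean(tau_hat) - mean(tau_true)),
    estimated_ate = mean(tau_hat),
    ite_r2 = if (sst == 0) NA_real_ else 1 - sum(err^2) / sst,
    ite_mae = mean(abs(err)),
    ite_std = sd(tau_hat)
  )
}

#' Interval (coverage) metrics
#'
#' Coverage is the proportion of true effects inside their per-unit
#' intervals; calibration error is the absolute deviation of the empirical
#' coverage from the nominal level.
#'
#' @param lower,upper per-unit interval bounds (`lower <= upper`).
#' @param tau_true ground-truth effects.
#' @param nominal nominal level (default 0.95).
#' @return a one-row tibble with `coverage`, `nominal`, `calibration_error`.
#' @export
interval_metrics <- function(lower, upper, tau_true, nominal = 0.95) {
  assert_that(all(lower <= upper), "crossed interval bounds")
  cov <- mean(tau_true >= lower & tau_true <= upper)
  tibble::tibble(coverage = cov, nominal = nominal,
                 calibration_error = abs(cov - nominal))
}

#' Binary classification metrics
#'
#' Confusion counts at the threshold; accuracy, precision, recall, F1 by
#' the standard formulas; AUC-ROC as the trapezoidal area under the
#' empirical ROC, computed via midrank statistics (equivalently the
#' Mann-Whitney probability with ties counted half).
#'
#' @param y_true binary labels.
#' @param y_prob scores/probabilities in `[0, 1]`.
#' @param threshold decision threshold (default 0.5; predictions >=
#'   threshold are positive).
#' @return a one-row tibble with `accuracy`, `precision`, `recall`, `f1`,
#'   `auc` (NA for single-class labels), `threshold`, `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
classification_metrics <- function(y_true, y_prob, threshold = 0.5) {
  assert_that(all(y_true %in% c(0, 1)), "`y_true` must be binary")
  pred <- as.integer(y_prob >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  tibble::tibble(accuracy = (tp + tn) / length(y_true),
                 precision = prec, recall = rec, f1 = f1,
                 auc = auc_roc(y_true, y_prob), threshold = threshold,
                 tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Area under the ROC curve (midrank ties)
#'
#' @inheritParams classification_metrics
#' @return AUC in `[0, 1]`, or NA when `y_true` has a single class.
#' @export
auc_roc <- function(y_true, y_prob) {
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(y_prob)            # midranks for ties
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
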