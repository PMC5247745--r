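#' ROC area under the curve with DeLong confidence interval
#'
#' AUC via the rank (Mann-Whitney) formulation with midrank handling of tied
#' scores: a tied event/non-event pair contributes 1/2. The standard error
#' comes from DeLong's placement-value variance; the confidence interval is
#' normal on the AUC scale, clipped to \[0, 1\], and the p-value tests
#' AUC = 0.5.
#'
#' @param data A data frame.
#' @param score Column with the (higher = riskier) score or risk.
#' @param truth Column with the event indicator (logical or 0/1).
#' @param conf_level Confidence level.
#' @return A one-row tibble: `auc`, `std_error`, `conf_low`, `conf_high`,
#'   `p_value`, `n_events`, `n_nonevents`.
#' @examples
#' d <- tibble::tibble(s = c(1, 2, 2, 3), y = c(0, 0, 1, 1))
#' eval_auc(d, s, y)
#' @export
eval_auc <- function(data, score, truth, conf_level = 0.95) {
  s <- rlang::eval_tidy(enquo(score), data)
  y <- check_labels(rlang::eval_tidy(enquo(truth), data))
  if (anyNA(s)) abort("missing scores")
  x <- s[y]; yy <- s[!y]
  m <- length(x); n <- length(yy)
  r_all <- rank(c(x, yy), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(yy, ties.method = "average")) / m
  auc <- mean(v10)
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- if (se > 0) 2 * pnorm(-abs((auc - 0.5) / se)) else NA_real_
  tibble(auc = auc, std_error = se,
         conf_low = max(auc - z * se, 0), conf_high = min(auc + z * se, 1),
         p_value = p, n_events = m, n_nonevents = n)
}

check_labels <- function(y) {
  if (anyNA(y)) abort("missing labels")
  if (is.numeric(y) && any(!y %in% c(0, 1))) abort("labels must be 0/1 or logical")
  y <- as.logical(y)
  if (all(y) || !any(y)) abort("both classes must be present")
  y
}

#' Optimal dichotomization cutoff by the Youden index
#'
#' Scans every observed score value as a candidate threshold (a subject is
#' test-positive when `score >= cutoff`) and returns the one maximising
#' Youden's J = sensitivity + specificity - 1. Ties are broken toward the
#' lower threshold, i.e. the more sensitive rule. A score that never beats
#' chance is flagged (`discriminates = FALSE` when the best J <= 0).
#'
#' @inheritParams eval_auc
#' @return A one-row tibble: `cutoff`, `sensitivity`, `specificity`,
#'   `youden`, `discriminates` (rates on the percent scale).
#' @export
youden_cutoff <- function(data, score, truth) {
  s <- rlang::eval_tidy(enquo(score), data)
  y <- check_labels(rlang::eval_tidy(enquo(truth), data))
  if (anyNA(s)) abort("missing scores")
  cand <- sort(unique(s))
  sens <- vapply(cand, function(c) mean(s[y] >= c), numeric(1))
  spec <- vapply(cand, function(c) mean(s[!y] < c), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # which() scans ascending: lowest threshold
  tibble(cutoff = cand[best], sensitivity = 100 * sens[best],
         specificity = 100 * spec[best], youden = j[best],
         discriminates = j[best] > 0)
}

#' Confusion-matrix rates
#'
#' Sensitivity, specificity, positive and negative predictive value from the
#' four cell counts, on the percent scale rounded to one decimal. A rate
#' whose denominator is zero is undefined and reported as `NA`, never as 0.
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (true/false
#'   positives/negatives).
#' @param digits Decimal places on the percent scale (default 1).
#' @return A one-row tibble: `sensitivity`, `specificity`, `ppv`, `npv`.
#' @examples
#' confusion_metrics(tp = 15, fp = 31, fn = 5, tn = 82)
#' @export
confusion_metrics <- function(tp, fp, fn, tn, digits = 1) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers")
  }
  rate <- function(num, den) {
    if (den == 0) NA_real_ else round(100 * num / den, digits)
  }
  tibble(sensitivity = rate(tp, tp + fn),
         specificity = rate(tn, tn + fp),
         ppv = rate(tp, tp + fp),
         npv = rate(tn, tn + fn))
}

#' Confusion counts of a thresholded score
#'
#' Cross-tabulates `score >= cutoff` against the event indicator.
#'
#' @inheritParams eval_auc
#' @param cutoff Threshold; a subject is test-positive when
#'   `score >= cutoff`.
#' @return A one-row tibble of counts: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(data, score, truth, cutoff) {
  s <- rlang::eval_tidy(enquo(score), data)
  y <- check_labels(rlang::eval_tidy(enquo(truth), data))
  pos <- s >= cutoff
  tibble(tp = sum(pos & y), fp = sum(pos & !y),
         fn = sum(!pos & y), tn = sum(!pos & !y))
}
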