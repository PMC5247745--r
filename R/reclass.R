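#' Integrated discrimination improvement (IDI)
#'
#' The difference in discrimination slopes between two risk models: (mean new
#' risk among events - mean new risk among non-events) minus the same
#' quantity for the old model. The p-value uses the paired standard-error
#' formulation: the variance of the per-subject risk differences is pooled
#' across the event and non-event groups.
#'
#' @param data A data frame.
#' @param new,old Columns of predicted event probabilities in (0, 1).
#' @param truth Event indicator column (logical or 0/1).
#' @return A one-row tibble: `idi`, `std_error`, `statistic`, `p_value`.
#' @examples
#' d <- tibble::tibble(new = c(0.6, 0.8, 0.2, 0.2),
#'                     old = c(0.5, 0.5, 0.3, 0.3),
#'                     y = c(1, 1, 0, 0))
#' idi(d, new, old, y)
#' @export
idi <- function(data, new, old, truth) {
  p_new <- rlang::eval_tidy(enquo(new), data)
  p_old <- rlang::eval_tidy(enquo(old), data)
  y <- check_labels(rlang::eval_tidy(enquo(truth), data))
  check_risks(p_new); check_risks(p_old)
  d <- p_new - p_old
  d_ev <- d[y]; d_ne <- d[!y]
  est <- mean(d_ev) - mean(d_ne)
  se <- sqrt(var_or0(d_ev) / length(d_ev) + var_or0(d_ne) / length(d_ne))
  z <- if (se > 0) est / se else NA_real_
  tibble(idi = est, std_error = se, statistic = z,
         p_value = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)))
}

check_risks <- function(p) {
  if (anyNA(p)) abort("missing risks")
  if (any(p <= 0 | p >= 1)) abort("risks must lie strictly in (0, 1)")
}

var_or0 <- function(x) if (length(x) > 1) var(x) else 0

#' Net reclassification improvement (NRI)
#'
#' Category-free (continuous) NRI by default: the net proportion of events
#' whose predicted risk rises under the new model plus the net proportion of
#' non-events whose risk falls, reported as a percentage (range -200% to
#' 200%). Ties (identical risks under both models) count toward neither
#' direction. Supplying `cutpoints` switches to the categorical version:
#' risks are binned at the cut-points and movement means changing category.
#'
#' The p-value uses the usual asymptotic variance of the two net proportions
#' (independent event and non-event components).
#'
#' @inheritParams idi
#' @param cutpoints Optional increasing vector of risk cut-points in (0, 1)
#'   defining categories for the categorical NRI.
#' @return A one-row tibble: `nri` (percent), `event_component` and
#'   `nonevent_component` (percent), `std_error` (percent), `statistic`,
#'   `p_value`.
#' @export
nri <- function(data, new, old, truth, cutpoints = NULL) {
  p_new <- rlang::eval_tidy(enquo(new), data)
  p_old <- rlang::eval_tidy(enquo(old), data)
  y <- check_labels(rlang::eval_tidy(enquo(truth), data))
  check_risks(p_new); check_risks(p_old)
  if (!is.null(cutpoints)) {
    brk <- c(0, sort(cutpoints), 1)
    p_new <- as.integer(cut(p_new, brk, include.lowest = TRUE))
    p_old <- as.integer(cut(p_old, brk, include.lowest = TRUE))
  }
  comp <- function(idx) {
    up <- mean(p_new[idx] > p_old[idx])
    down <- mean(p_new[idx] < p_old[idx])
    net <- up - down
    list(net = net, var = (up + down - net^2) / sum(idx))
  }
  ev <- comp(y); ne <- comp(!y)
  est <- ev$net + (-ne$net)
  se <- sqrt(ev$var + ne$var)
  z <- if (se > 0) est / se else NA_real_
  tibble(nri = 100 * est,
         event_component = 100 * ev$net,
         nonevent_component = -100 * ne$net,
         std_error = 100 * se, statistic = z,
         p_value = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)))
}
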