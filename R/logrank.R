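#' Two-group log-rank test
#'
#' Standard two-sample log-rank test with the hypergeometric variance at each
#' distinct event time. The chi-square statistic (1 df) is invariant to the
#' group labelling; the signed square root reported in `direction` is
#' positive when the first group (by sort order of the labels) has more
#' events than expected, i.e. worse survival.
#'
#' @inheritParams km_curve
#' @param group Column with exactly two distinct values.
#' @return An object of class `logrank_test`: a list with `statistic`, `df`,
#'   `p_value`, `direction`, and a `groups` tibble of observed and expected
#'   event counts.
#' @examples
#' d <- tibble::tibble(t = c(1, 2, 3, 4), e = TRUE, g = c("a", "a", "b", "b"))
#' logrank_test(d, t, e, g)
#' @export
logrank_test <- function(data, time = followup_months, event = vlraf_event,
                         group) {
  t <- rlang::eval_tidy(enquo(time), data)
  d <- rlang::eval_tidy(enquo(event), data)
  g <- rlang::eval_tidy(enquo(group), data)
  check_surv_input(t, d)
  d <- as.logical(d)
  lev <- sort(unique(g))
  if (length(lev) != 2) abort("log-rank test requires exactly two groups")
  if (min(table(g)) < 1) abort("one group is empty")
  g1 <- g == lev[1]
  ev_times <- sort(unique(t[d]))
  o1 <- e1 <- v <- 0
  for (u in ev_times) {
    at_risk <- t >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    dd <- sum(t == u & d)
    d1 <- sum(t == u & d & g1)
    o1 <- o1 + d1
    e1 <- e1 + dd * n1 / n
    if (n > 1) v <- v + dd * (n1 / n) * (1 - n1 / n) * (n - dd) / (n - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  total <- sum(d)
  structure(list(
    statistic = stat, df = 1L,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    direction = if (v > 0) sign(o1 - e1) * sqrt(stat) else 0,
    groups = tibble(group = lev,
                    n = c(sum(g1), sum(!g1)),
                    observed = c(o1, total - o1),
                    expected = c(e1, total - e1))
  ), class = "logrank_test")
}

#' @export
tidy.logrank_test <- function(x, ...) x$groups

#' @export
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-group log-rank test\n")
  cat(sprintf("  chi-square = %.4f (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  print(x$groups)
  invisible(x)
}
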