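#' Kaplan-Meier product-limit curve
#'
#' Computes the product-limit survival estimate with the Greenwood variance.
#' Rows are emitted at every distinct observed time (event or censoring);
#' survival drops only at event times, and subjects censored at an event time
#' remain in that time's risk set (censoring after events at tied times).
#'
#' @param data A data frame with one row per subject.
#' @param time,event Columns holding follow-up time (> 0) and the event
#'   indicator (logical or 0/1). Defaults match the cohort schema.
#' @param group Optional column defining strata; the curve is then computed
#'   per stratum.
#' @return A tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `std_err` (standard error of the
#'   survival estimate), `var` (Greenwood variance) and, when stratified,
#'   `group`.
#' @examples
#' km_curve(tibble::tibble(followup_months = c(5, 10, 15),
#'                         vlraf_event = c(TRUE, TRUE, FALSE)))
#' @export
km_curve <- function(data, time = followup_months, event = vlraf_event,
                     group = NULL) {
  t <- rlang::eval_tidy(enquo(time), data)
  d <- rlang::eval_tidy(enquo(event), data)
  g_quo <- enquo(group)
  g <- if (rlang::quo_is_null(g_quo)) NULL else rlang::eval_tidy(g_quo, data)
  check_surv_input(t, d)
  d <- as.logical(d)
  if (is.null(g)) {
    out <- km_engine(t, d)
  } else {
    out <- dplyr::bind_rows(lapply(split(seq_along(t), g), function(idx) {
      cbind(tibble(group = g[idx[1]]), km_engine(t[idx], d[idx]))
    }))
    out <- as_tibble(out)
  }
  structure(out, class = c("km_curve", class(out)),
            n = length(t), n_events = sum(d), max_time = max(t))
}

check_surv_input <- function(t, d) {
  if (length(t) == 0) abort("empty survival input")
  if (length(t) != length(d)) abort("time and event lengths differ")
  if (anyNA(t) || anyNA(d)) abort("missing values in survival input")
  if (any(t <= 0)) abort("follow-up times must be > 0")
  if (is.numeric(d) && any(!d %in% c(0, 1))) abort("event must be 0/1 or logical")
}

km_engine <- function(t, d) {
  ts <- sort(unique(t))
  n_risk <- vapply(ts, function(u) sum(t >= u), numeric(1))
  n_event <- vapply(ts, function(u) sum(t == u & d), numeric(1))
  n_censor <- vapply(ts, function(u) sum(t == u & !d), numeric(1))
  frac <- ifelse(n_risk > 0, 1 - n_event / n_risk, 1)
  surv <- cumprod(frac)
  gw_term <- ifelse(n_event > 0 & n_risk > n_event,
                    n_event / (n_risk * (n_risk - n_event)),
                    ifelse(n_event == n_risk & n_event > 0, Inf, 0))
  gw <- surv^2 * cumsum(gw_term)
  gw[surv == 0] <- 0  # absorbing state: estimate exactly 0
  tibble(time = ts, n_risk = as.integer(n_risk),
         n_event = as.integer(n_event), n_censor = as.integer(n_censor),
         survival = surv, std_err = sqrt(gw), var = gw)
}

km_surv_at <- function(curve, t) {
  # step-function lookup of S(t) and Greenwood variance (single stratum)
  idx <- findInterval(t, curve$time)
  s <- c(1, curve$survival)[idx + 1]
  v <- c(0, curve$var)[idx + 1]
  list(surv = s, var = v)
}

#' Cumulative incidence from a Kaplan-Meier curve
#'
#' Returns `1 - S(t)` with a 95% confidence interval on the plain (normal)
#' scale from the Greenwood variance. Times beyond the last observed time are
#' answered with the last estimate and flagged as extrapolated.
#'
#' @param curve A single-stratum [km_curve()].
#' @param at Numeric vector of times (>= 0).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with `at`, `estimate`, `conf_low`, `conf_high`,
#'   `extrapolated`.
#' @export
cum_incidence <- function(curve, at, conf_level = 0.95) {
  stopifnot(inherits(curve, "km_curve"))
  if ("group" %in% names(curve)) {
    abort("cum_incidence expects a single-stratum curve")
  }
  if (any(at < 0)) abort("times must be >= 0")
  z <- qnorm(1 - (1 - conf_level) / 2)
  s <- km_surv_at(curve, pmin(at, max(curve$time)))
  est <- 1 - s$surv
  se <- sqrt(s$var)
  tibble(at = at, estimate = est,
         conf_low = pmax(est - z * se, 0),
         conf_high = pmin(est + z * se, 1),
         extrapolated = at > attr(curve, "max_time"))
}

#' @export
tidy.km_curve <- function(x, ...) {
  z <- qnorm(0.975)
  out <- as_tibble(x)
  out$conf_low <- pmax(out$survival - z * out$std_err, 0)
  out$conf_high <- pmin(out$survival + z * out$std_err, 1)
  out
}

#' @export
glance.km_curve <- function(x, ...) {
  tibble(n = attr(x, "n"), n_events = attr(x, "n_events"),
         max_time = attr(x, "max_time"))
}

#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tidy.km_curve(object)
  has_group <- "group" %in% names(df)
  starts <- if (has_group) {
    dplyr::mutate(dplyr::distinct(df, .data$group),
                  time = 0, survival = 1, conf_low = 1, conf_high = 1)
  } else {
    tibble(time = 0, survival = 1, conf_low = 1, conf_high = 1)
  }
  df <- dplyr::bind_rows(starts, df)
  mapping <- if (has_group) {
    ggplot2::aes(x = .data$time, y = .data$survival,
                 colour = factor(.data$group))
  } else {
    ggplot2::aes(x = .data$time, y = .data$survival)
  }
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months since ablation", y = "Recurrence-free survival",
                  colour = "Stratum") +
    ggplot2::theme_minimal()
}
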