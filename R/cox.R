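#' Univariate Cox proportional-hazards fit
#'
#' Maximises the Cox partial likelihood for a single covariate by Newton's
#' method with step-halving, using the Efron correction for tied event
#' times. Convergence is declared when the Newton update falls below `tol`
#' (default 1e-9, at most 50 iterations). A monotone partial likelihood
#' (complete separation, e.g. all events in one arm of a binary covariate)
#' cannot be maximised in the interior; the fit is then returned with
#' `converged = FALSE` and the runaway `direction` of the coefficient.
#'
#' The Wald statistic drives the confidence interval and p-value. The score
#' statistic evaluated at zero is also reported; for a binary covariate
#' without tied event times it coincides with the log-rank chi-square.
#'
#' @inheritParams km_curve
#' @param covariate Numeric or logical column; must not be constant.
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @return An object of class `cox_fit`: `term`, `beta`, `se`, `hr`,
#'   `conf_low`, `conf_high`, `p_value`, `score_stat`, `converged`,
#'   `direction`, `iter`, `n`, `n_events`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_candidates = 300), seed = 2)
#' fit <- cox_fit(cohort, eraf)
#' tidy(fit)
#' @export
cox_fit <- function(data, covariate, time = followup_months,
                    event = vlraf_event, conf_level = 0.95) {
  x_quo <- enquo(covariate)
  x <- rlang::eval_tidy(x_quo, data)
  t <- rlang::eval_tidy(enquo(time), data)
  d <- rlang::eval_tidy(enquo(event), data)
  check_surv_input(t, d)
  fit <- cox_engine(as.numeric(x), t, as.logical(d), conf_level = conf_level)
  fit$term <- as_name(x_quo)
  fit
}

cox_engine <- function(x, t, d, max_iter = 50, tol = 1e-9,
                       conf_level = 0.95) {
  n <- length(x)
  if (sum(d) < 1) abort("no events: Cox fit is undefined")
  if (length(unique(x)) < 2) abort("constant covariate (degenerate input)")
  ord <- order(t)
  x <- x[ord]; t <- t[ord]; d <- d[ord]
  # centre the covariate for numerical stability; beta is unaffected
  xc <- x - mean(x)
  ev_times <- unique(t[d])
  first_idx <- findInterval(ev_times, t, left.open = TRUE) + 1
  death_sets <- lapply(ev_times, function(u) which(t == u & d))
  llgh <- function(beta) {
    w <- exp(xc * beta)
    xw <- xc * w; x2w <- xc^2 * w
    rs0 <- rev(cumsum(rev(w)))
    rs1 <- rev(cumsum(rev(xw)))
    rs2 <- rev(cumsum(rev(x2w)))
    ll <- g <- h <- 0
    for (j in seq_along(ev_times)) {
      D <- death_sets[[j]]
      dd <- length(D)
      i0 <- first_idx[j]
      l <- (seq_len(dd) - 1) / dd
      den <- rs0[i0] - l * sum(w[D])
      num1 <- rs1[i0] - l * sum(xw[D])
      num2 <- rs2[i0] - l * sum(x2w[D])
      ll <- ll + sum(xc[D]) * beta - sum(log(den))
      g <- g + sum(xc[D]) - sum(num1 / den)
      h <- h - sum(num2 / den - (num1 / den)^2)
    }
    list(ll = ll, g = g, h = h)
  }
  at0 <- llgh(0)
  score_stat <- if (at0$h < 0) at0$g^2 / (-at0$h) else 0
  beta <- 0
  cur <- at0
  converged <- FALSE
  iter <- 0L
  boundary <- FALSE
  for (it in seq_len(max_iter)) {
    iter <- it
    if (cur$h >= 0) { boundary <- TRUE; break }
    step <- -cur$g / cur$h
    new_beta <- beta + step
    new <- llgh(new_beta)
    halvings <- 0
    while (new$ll < cur$ll - 1e-12 && halvings < 25) {
      step <- step / 2
      new_beta <- beta + step
      new <- llgh(new_beta)
      halvings <- halvings + 1
    }
    moved <- abs(new_beta - beta)
    beta <- new_beta
    cur <- new
    if (abs(beta) > 15) { boundary <- TRUE; break }
    if (moved < tol) { converged <- TRUE; break }
  }
  se <- if (cur$h < 0) sqrt(-1 / cur$h) else NA_real_
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (boundary || !converged) {
    structure(list(
      term = NA_character_, beta = beta, se = NA_real_, hr = exp(beta),
      conf_low = NA_real_, conf_high = NA_real_, p_value = NA_real_,
      score_stat = score_stat, converged = FALSE,
      direction = sign(if (beta != 0) beta else cur$g), iter = iter,
      n = n, n_events = sum(d)), class = "cox_fit")
  } else {
    structure(list(
      term = NA_character_, beta = beta, se = se, hr = exp(beta),
      conf_low = exp(beta - z * se), conf_high = exp(beta + z * se),
      p_value = 2 * pnorm(-abs(beta / se)),
      score_stat = score_stat, converged = TRUE, direction = sign(beta),
      iter = iter, n = n, n_events = sum(d)), class = "cox_fit")
  }
}

#' @export
tidy.cox_fit <- function(x, ...) {
  tibble(term = x$term, estimate = x$beta, std_error = x$se,
         hr = x$hr, conf_low = x$conf_low, conf_high = x$conf_high,
         p_value = x$p_value, converged = x$converged)
}

#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, score_stat = x$score_stat,
         iter = x$iter, converged = x$converged)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Univariate Cox fit: %s (n = %d, events = %d)\n",
              x$term %||% "<covariate>", x$n, x$n_events))
  if (x$converged) {
    cat(sprintf("  HR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                x$hr, x$conf_low, x$conf_high, x$p_value))
  } else {
    cat(sprintf("  did not converge (monotone likelihood, direction %+d)\n",
                x$direction))
  }
  invisible(x)
}
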