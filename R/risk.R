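#' Calibrate integer scores to event probabilities
#'
#' Fits a one-variable logistic regression of the event indicator on the
#' score, the bridge needed to place integer score points on the probability
#' scale for reclassification (IDI) and decision-curve analysis. When the fit
#' separates (some score value perfectly splits the classes, so the MLE is
#' at infinity) the mapping falls back to the empirical per-stratum event
#' rates, clamped away from 0 and 1, with linear interpolation between
#' observed score values.
#'
#' @inheritParams eval_auc
#' @return An object of class `risk_mapping`: `method` (`"logistic"` or
#'   `"empirical"`), `intercept` and `slope` (logistic only), `table`
#'   (empirical only), `separated`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_candidates = 300), seed = 3)
#' d <- dplyr::left_join(score_mb_later(cohort), cohort, by = "id")
#' rm <- fit_risk_mapping(d, mb_later, vlraf_event)
#' predict(rm, 0:6)
#' @export
fit_risk_mapping <- function(data, score, truth) {
  s <- rlang::eval_tidy(enquo(score), data)
  y <- check_labels(rlang::eval_tidy(enquo(truth), data))
  if (anyNA(s)) abort("missing scores")
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ s, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  slope <- unname(coef(fit)[2])
  fitted_p <- stats::fitted(fit)
  if (!separated && (is.na(slope) || abs(slope) > 10 ||
                     any(fitted_p < 1e-8) || any(fitted_p > 1 - 1e-8))) {
    separated <- TRUE
  }
  if (!separated) {
    structure(list(method = "logistic",
                   intercept = unname(coef(fit)[1]),
                   slope = slope,
                   table = NULL, separated = FALSE),
              class = "risk_mapping")
  } else {
    eps <- 1e-6
    tab <- dplyr::summarise(
      dplyr::group_by(tibble(s = s, y = y), .data$s),
      risk = pmin(pmax(mean(.data$y), eps), 1 - eps), .groups = "drop")
    structure(list(method = "empirical", intercept = NA_real_,
                   slope = NA_real_,
                   table = dplyr::arrange(tab, .data$s), separated = TRUE),
              class = "risk_mapping")
  }
}

#' @export
predict.risk_mapping <- function(object, newdata, ...) {
  s <- if (is.data.frame(newdata)) newdata[[1]] else newdata
  if (object$method == "logistic") {
    plogis(object$intercept + object$slope * s)
  } else {
    tab <- object$table
    if (nrow(tab) == 1) rep(tab$risk, length(s))
    else stats::approx(tab$s, tab$risk, xout = s, rule = 2)$y
  }
}

#' @export
print.risk_mapping <- function(x, ...) {
  if (x$method == "logistic") {
    cat(sprintf("Logistic risk mapping: logit(p) = %.4f + %.4f * score\n",
                x$intercept, x$slope))
  } else {
    cat("Empirical risk mapping (logistic fit separated):\n")
    print(x$table)
  }
  invisible(x)
}
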