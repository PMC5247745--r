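#' Decision-curve analysis
#'
#' Net benefit of acting on a risk model across threshold probabilities:
#' `NB(pt) = TP/n - (FP/n) * pt / (1 - pt)`, where a patient is flagged when
#' their predicted risk is at least `pt`. The reference strategies are
#' treat-all (`prevalence - (1 - prevalence) * pt / (1 - pt)`) and treat-none
#' (net benefit identically 0).
#'
#' @inheritParams idi
#' @param risk Column of predicted event probabilities in (0, 1).
#' @param thresholds Threshold probabilities in (0, 1); default 0.05 to 0.50
#'   in steps of 0.01.
#' @return A tibble of class `decision_curve`, long over strategies:
#'   `threshold`, `strategy` (`model`, `treat_all`, `treat_none`),
#'   `net_benefit`.
#' @examples
#' d <- tibble::tibble(r = c(0.9, 0.6, 0.3, 0.3, 0.2, 0.2, 0.1, 0.1, 0.1, 0.1),
#'                     y = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
#' decision_curve(d, r, y, thresholds = 0.2)
#' @export
decision_curve <- function(data, risk, truth,
                           thresholds = seq(0.05, 0.50, by = 0.01)) {
  p <- rlang::eval_tidy(enquo(risk), data)
  y <- check_labels(rlang::eval_tidy(enquo(truth), data))
  check_risks(p)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("thresholds must lie strictly in (0, 1)")
  }
  n <- length(y)
  prev <- mean(y)
  nb_model <- vapply(thresholds, function(pt) {
    flag <- p >= pt
    sum(flag & y) / n - sum(flag & !y) / n * pt / (1 - pt)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  out <- dplyr::bind_rows(
    tibble(threshold = thresholds, strategy = "model", net_benefit = nb_model),
    tibble(threshold = thresholds, strategy = "treat_all", net_benefit = nb_all),
    tibble(threshold = thresholds, strategy = "treat_none", net_benefit = 0)
  )
  structure(out, class = c("decision_curve", class(out)), prevalence = prev)
}

#' @export
autoplot.decision_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
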